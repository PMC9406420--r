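# Shared helpers: error conditions, RNG hygiene, small array utilities.

csn_error <- function(msg, class, call = sys.call(-1)) {
  stop(structure(class = c(class, "csn_error", "error", "condition"),
                 list(message = msg, call = call)))
}

#' @noRd
csn_config_error <- function(msg) csn_error(msg, "csn_config_error")
#' @noRd
csn_data_error <- function(msg) csn_error(msg, "csn_data_error")
#' @noRd
csn_dependency_error <- function(msg) csn_error(msg, "csn_dependency_error")

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream (same-seed determinism contract used throughout the package).
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# coerce a single H x W matrix (or H x W x 1 array) to the internal
# (H, W, C, N) tensor layout
as_tensor <- function(x) {
  if (is.matrix(x)) {
    dim(x) <- c(dim(x), 1L, 1L)
    return(x)
  }
  d <- dim(x)
  if (length(d) == 3L) {
    dim(x) <- c(d, 1L)
    return(x)
  }
  if (length(d) == 4L) return(x)
  csn_data_error("expected a matrix or a 3-/4-dimensional array")
}

# stack a list of H x W matrices into an (H, W, 1, N) batch tensor
stack_batch <- function(mats) {
  d <- dim(mats[[1]])
  out <- array(0, c(d[1], d[2], 1L, length(mats)))
  for (i in seq_along(mats)) out[, , 1L, i] <- mats[[i]]
  out
}

is_binary <- function(m) all(m %in% c(0, 1))

`%||%` <- function(a, b) if (is.null(a)) b else a
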