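# The reference 54-row layer schedule of the twin-SegNet architecture,
# written out literally as data (not derived from the graph builder) so the
# realized model can be checked against it layer by layer.

#' Reference layer schedule
#'
#' The 54-row layer table of the Connected-SegNets architecture (input,
#' Conv1..Conv27, pooling/unpooling and concatenation stages, output), with
#' output shapes computed for the given input size and channel width.  One
#' printed shape in the original table (the third SegNet2 concatenation,
#' row 34) is inconsistent with its neighbours, which force 2x the third
#' encoder width at 1/8 spatial scale; the corrected shape is used and the
#' row is flagged in the `corrected` column.  The duplicated Conv13 row is
#' kept (rows 24-25) to preserve the published numbering; both describe the
#' same layer.
#'
#' @param config A [model_config()].
#' @return Data frame with columns `no`, `name`, `kind`, `out_h`, `out_w`,
#'   `out_c`, `filter`, `n_filters`, `n_layers`, `dilation`, `corrected`.
#' @export
connected_segnet_schedule <- function(config = model_config()) {
  s <- config$input_size
  ch <- config$channel_schedule
  c1 <- ch[1]; c2 <- ch[2]; c3 <- ch[3]; c4 <- ch[4]; c5 <- ch[5]
  s2 <- s / 2; s4 <- s / 4; s8 <- s / 8; s16 <- s / 16; s32 <- s / 32
  r <- function(no, name, kind, hw, c, filter = "", nf = NA, nl = NA,
                dil = 1, corr = FALSE)
    data.frame(no = no, name = name, kind = kind, out_h = hw, out_w = hw,
               out_c = c, filter = filter, n_filters = nf, n_layers = nl,
               dilation = dil, corrected = corr, stringsAsFactors = FALSE)
  rows <- list(
    r(1, "Input", "input", s, 1, nl = 1),
    r(2, "Conv1", "conv_block", s, c1, "3x3", c1, 2),
    r(3, "Maxpool", "pool", s2, c1, nl = 1),
    r(4, "Conv2", "conv_block", s2, c2, "3x3", c2, 2),
    r(5, "Maxpool", "pool", s4, c2, nl = 1),
    r(6, "Conv3", "conv_block", s4, c3, "3x3", c3, 3),
    r(7, "Maxpool", "pool", s8, c3, nl = 1),
    r(8, "Conv4", "conv_block", s8, c4, "3x3", c4, 3),
    r(9, "Maxpool", "pool", s16, c4, nl = 1),
    r(10, "Conv5", "conv_block", s16, c5, "3x3", c5, 3),
    r(11, "Maxpool", "pool", s32, c5, nl = 1),
    r(12, "Upsampling", "unpool", s16, c5, nl = 1),
    r(13, "Conv6", "conv_block", s16, c5, "3x3", c5, 3),
    r(14, "Upsampling", "unpool", s8, c5, nl = 1),
    r(15, "Conv7", "conv_block", s8, c4, "3x3", c4, 2),
    r(16, "Conv8", "conv_block", s8, c3, "3x3", c3, 1),
    r(17, "Upsampling", "unpool", s4, c3, nl = 1),
    r(18, "Conv9", "conv_block", s4, c3, "3x3", c3, 2),
    r(19, "Conv10", "conv_block", s4, c2, "3x3", c2, 1),
    r(20, "Upsampling", "unpool", s2, c2, nl = 1),
    r(21, "Conv11", "conv_block", s2, c2, "3x3", c2, 2),
    r(22, "Conv12", "conv_block", s2, c1, "3x3", c1, 1),
    r(23, "Upsampling", "unpool", s, c1, nl = 1),
    r(24, "Conv13", "conv_block", s, c1, "3x3", c1, 1),
    r(25, "Conv13", "conv_block", s, c1),
    r(26, "Conv14", "conv_block", s, c1, "3x3", c1, 2),
    r(27, "Maxpool", "pool", s2, c1, nl = 1),
    r(28, "Concatenate", "concat", s2, 2 * c1, nl = 1),
    r(29, "Conv15", "conv_block", s2, c2, "3x3", c2, 2),
    r(30, "Maxpool", "pool", s4, c2, nl = 1),
    r(31, "Concatenate", "concat", s4, 2 * c2, nl = 1),
    r(32, "Conv16", "conv_block", s4, c3, "3x3", c3, 3),
    r(33, "Maxpool", "pool", s8, c3, nl = 1),
    r(34, "Concatenate", "concat", s8, 2 * c3, nl = 1, corr = TRUE),
    r(35, "Conv17", "conv_block", s8, c4, "3x3", c4, 3),
    r(36, "Maxpool", "pool", s16, c4, nl = 1),
    r(37, "Concatenate", "concat", s16, 2 * c4, nl = 1),
    r(38, "Conv18", "conv_block", s16, c5, "3x3", c5, 3),
    r(39, "Maxpool", "pool", s32, c5, nl = 1),
    r(40, "Upsampling", "unpool", s16, c5, nl = 1),
    r(41, "Conv19", "conv_block", s16, c5, "3x3", c5, 3),
    r(42, "Upsampling", "unpool", s8, c5, nl = 1),
    r(43, "Conv20", "conv_block", s8, c4, "3x3", c4, 2),
    r(44, "Conv21", "conv_block", s8, c3, "3x3", c3, 1),
    r(45, "Upsampling", "unpool", s4, c3, nl = 1),
    r(46, "Conv22", "conv_block", s4, c3, "3x3", c3, 2),
    r(47, "Conv23", "conv_block", s4, c2, "3x3", c2, 1),
    r(48, "Upsampling", "unpool", s2, c2, nl = 1),
    r(49, "Conv24", "conv_block", s2, c2, "3x3", c2, 2),
    r(50, "Conv25", "conv_block", s2, c1, "3x3", c1, 1),
    r(51, "Upsampling", "unpool", s, c1, nl = 1),
    r(52, "Conv26", "conv_block", s, c1, "3x3", c1, 1),
    r(53, "Conv27", "conv_block", s, c1, "3x3", c1, 1, dil = config$dilation_rate),
    r(54, "Output", "conv_block", s, 1, "1x1", 1, 1))
  do.call(rbind, rows)
}

#' Realized per-layer output shapes
#'
#' Runs one forward pass (batch of 1) and returns, for every graph node with
#' a schedule row number, the realized output dimensions, aligned with
#' [connected_segnet_schedule()].
#'
#' @param model A `segnet_model`.
#' @return Data frame `no`, `node`, `name`, `out_h`, `out_w`, `out_c`.
#' @export
realized_layer_shapes <- function(model) {
  sz <- model$config$input_size
  fw <- segnet_forward(model, matrix(0.5, sz, sz))
  rows <- lapply(model$nodes, function(nd) {
    if (is.na(nd$table_row)) return(NULL)
    d <- fw$shapes[[nd$id]]
    data.frame(no = nd$table_row, node = nd$id, name = nd$name,
               out_h = d[1], out_w = d[2], out_c = d[3],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$no), ]
}

#' @export
print.segnet_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Connected-SegNets model (%d SegNet%s)\n", cfg$n_segnets,
              if (cfg$n_segnets > 1) "s" else ""))
  cat(sprintf("  input %dx%dx1, channel schedule %s, dilation head %d\n",
              cfg$input_size, cfg$input_size,
              paste(cfg$channel_schedule, collapse = "/"),
              cfg$dilation_rate))
  np <- sum(vapply(x$nodes, function(nd)
    sum(vapply(nd$units, function(u)
      length(u$W) + length(u$b) +
        if (u$bn) 2L * length(u$gamma) else 0L, 0L)), 0L))
  cat(sprintf("  %d layers, %s parameters\n", length(x$nodes),
              format(np, big.mark = ",")))
  invisible(x)
}

#' Text summary mirroring the layer table
#'
#' @param object A `segnet_model`.
#' @param ... Unused.
#' @export
summary.segnet_model <- function(object, ...) {
  sch <- connected_segnet_schedule(object$config)
  sch$output <- sprintf("%d x %d x %d", sch$out_h, sch$out_w, sch$out_c)
  sch[, c("no", "name", "output", "filter", "n_filters", "n_layers",
          "dilation")]
}

# ---- checkpointing (layer-name-keyed weights + config) ----

model_weights <- function(model) {
  lapply(model$nodes, function(nd) {
    if (nd$repeats == 0L) return(NULL)
    lapply(nd$units, function(u) {
      w <- list(W = u$W, b = u$b)
      if (u$bn) w <- c(w, list(gamma = u$gamma, beta = u$beta,
                               rmean = u$rmean, rvar = u$rvar))
      w
    })
  })
}

set_model_weights <- function(model, weights) {
  for (id in names(model$nodes)) {
    nd <- model$nodes[[id]]
    if (nd$repeats == 0L) next
    for (r in seq_len(nd$repeats)) {
      w <- weights[[id]][[r]]
      u <- nd$units[[r]]
      u$W <- w$W; u$b <- w$b
      if (u$bn) {
        u$gamma <- w$gamma; u$beta <- w$beta
        u$rmean <- w$rmean; u$rvar <- w$rvar
      }
    }
  }
  invisible(model)
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single RDS archive holding the model configuration and
#' all weights keyed by layer name.
#'
#' @param model A `segnet_model`.
#' @param path Checkpoint file.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(config = unclass(model$config),
               weights = model_weights(model)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path))
    csn_dependency_error(sprintf("checkpoint '%s' not found", path))
  ck <- readRDS(path)
  cfg <- do.call(model_config, ck$config[c("input_size", "base_channels",
                                           "width_multiplier", "dilation_rate",
                                           "final_activation", "bn_order",
                                           "n_segnets", "seed")])
  model <- build_architecture(cfg)
  set_model_weights(model, ck$weights)
  model
}
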