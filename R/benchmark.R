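# The package's reference desk-scale experiment: phantom generation ->
# CLAHE -> training -> held-out evaluation, all in memory.

#' Run the desk-scale phantom benchmark
#'
#' Generates 64 x 64 phantom datasets (200 train / 50 validation / 50 test
#' by default), applies CLAHE to every image, trains the 1/8-width
#' Connected-SegNets for a short fixed schedule (Adam, learning rate 1e-3,
#' batch 4) and evaluates on the held-out test set.  Everything is
#' deterministic in `seed`.
#'
#' @param seed Master seed (phantom content, weight init and shuffling are
#'   all derived from it).
#' @param n_train,n_val,n_test Dataset sizes.
#' @param epochs Training epochs (fixed schedule, no early stop at this
#'   length since patience exceeds it).
#' @param learning_rate Adam step size for the narrow model (1e-3 scale,
#'   suited to the short schedule; the full-width default stays at the
#'   published 1e-4).
#' @param output_bias Initial bias of the output convolution;
#'   `qlogis(0.12) ~ -2` starts predictions at the foreground prior of the
#'   phantoms, a standard initialization for class-imbalanced segmentation.
#' @param clahe A [clahe_params()] applied identically to all splits.
#' @return List with `train_result`, `eval` (an `eval_result`; `mean_dice`
#'   is the headline number) and `datasets` sizes.
#' @examples
#' \dontrun{
#' bench <- run_tiny_benchmark(seed = 1)
#' bench$eval$mean_dice
#' }
#' @export
run_tiny_benchmark <- function(seed = 1L, n_train = 200L, n_val = 50L,
                               n_test = 50L, epochs = 12L,
                               learning_rate = 3e-3, output_bias = -2,
                               clahe = clahe_params()) {
  seed <- as.integer(seed)
  spec <- phantom_spec(size = 64L)
  make_split <- function(n, offset) {
    pairs <- generate_dataset(n, seed * 1000L + offset, spec)$pairs
    lapply(pairs, function(p)
      list(image = apply_clahe(p$image, clahe), mask = p$mask))
  }
  train <- make_split(n_train, 0L)
  val <- make_split(n_val, 500L)
  test <- make_split(n_test, 700L)
  model <- build_architecture(tiny_model_config(seed = seed))
  model$nodes$out$units[[1]]$b <- output_bias
  tc <- train_config(learning_rate = learning_rate, batch_size = 4L,
                     max_epochs = epochs, patience = 20L, seed = seed)
  tr <- train_segnet(model, train, val, tc)
  ev <- evaluate_segnet(tr$model, test)
  list(train_result = tr, eval = ev,
       datasets = c(train = n_train, val = n_val, test = n_test))
}
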