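# Training loop: Adam with the published hyperparameters, soft IoU loss,
# and early stopping driven by validation-loss tracking.

#' Training configuration
#'
#' Defaults follow the published setup: Adam with learning rate 1e-4,
#' batch size 4, patience ("ActStepSetting") of 20 epochs on validation
#' loss.
#'
#' @param learning_rate Adam step size (> 0).
#' @param batch_size Mini-batch size (>= 1).
#' @param max_epochs Epoch cap (early stopping usually halts sooner).
#' @param patience Consecutive non-improving validation epochs tolerated
#'   before stopping (>= 0).
#' @param seed Seed fixing shuffling (weight initialization is seeded in
#'   [model_config()]).
#' @param threshold Binarization threshold for validation Dice/IoU.
#' @param verbose Print one line per epoch.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 4L,
                         max_epochs = 200L, patience = 20L, seed = 42L,
                         threshold = 0.5, verbose = FALSE) {
  if (learning_rate <= 0) csn_config_error("learning_rate must be > 0")
  if (batch_size < 1) csn_config_error("batch_size must be >= 1")
  if (patience < 0) csn_config_error("patience must be >= 0")
  if (max_epochs < 1) csn_config_error("max_epochs must be >= 1")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed),
                 threshold = threshold, verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Early-stopping state and update
#'
#' Validation-loss tracking: a strictly improving loss resets the
#' non-improvement counter and records the new best; otherwise the counter
#' increments, and once it exceeds the patience the `stopped` flag is
#' raised.  The best score is non-increasing over updates; ties count as
#' non-improving.
#'
#' @param patience Allowed consecutive non-improving updates.
#' @return `early_stop_state`: list with `best` (best validation loss so
#'   far), `repeats` (consecutive non-improving updates since the last
#'   best), `patience`, `stopped`.
#' @export
early_stop_state <- function(patience = 20L) {
  structure(list(best = Inf, repeats = 0L, patience = as.integer(patience),
                 stopped = FALSE), class = "early_stop_state")
}

#' @rdname early_stop_state
#' @param state An `early_stop_state`.
#' @param latest_val_loss Finite validation loss of the latest epoch.
#' @export
early_stop_update <- function(state, latest_val_loss) {
  if (!is.finite(latest_val_loss))
    csn_data_error("validation loss is not finite; aborting tracking")
  if (latest_val_loss < state$best) {
    state$best <- latest_val_loss
    state$repeats <- 0L
  } else {
    state$repeats <- state$repeats + 1L
  }
  if (state$repeats > state$patience) state$stopped <- TRUE
  state
}

# mean per-sample soft IoU loss over a batch + its gradient
batch_loss_grad <- function(pred, target) {
  N <- dim(pred)[4]
  loss <- 0
  grad <- array(0, dim(pred))
  for (n in seq_len(N)) {
    p <- pred[, , , n, drop = FALSE]
    g <- target[, , , n, drop = FALSE]
    loss <- loss + soft_iou_loss(p, g)
    grad[, , , n] <- soft_iou_loss_grad(p, g) / N
  }
  list(loss = loss / N, grad = grad)
}

adam_update_model <- function(model, lr, t) {
  for (nd in model$nodes) {
    for (u in nd$units) {
      pars <- c("W", "b", if (u$bn) c("gamma", "beta"))
      if (is.null(u$opt))
        u$opt <- sapply(pars, function(pn)
          list(m = numeric(length(u[[pn]])), v = numeric(length(u[[pn]]))),
          simplify = FALSE)
      for (pn in pars) {
        g <- u[[paste0("d", pn)]]
        if (is.null(g)) next
        u[[pn]] <- adam_step(u[[pn]], g, u$opt[[pn]], lr, t)
      }
    }
  }
}

# forward a list of samples in batches, inference mode
predict_samples <- function(model, samples, batch_size = 4L) {
  preds <- vector("list", length(samples))
  i <- 1L
  while (i <= length(samples)) {
    j <- min(i + batch_size - 1L, length(samples))
    x <- stack_batch(lapply(samples[i:j], `[[`, "image"))
    p <- segnet_forward(model, x)$pred
    for (k in i:j) preds[[k]] <- p[, , 1L, k - i + 1L]
    i <- j + 1L
  }
  preds
}

eval_pass <- function(model, samples, batch_size, threshold) {
  preds <- predict_samples(model, samples, batch_size)
  losses <- vapply(seq_along(samples), function(k)
    soft_iou_loss(preds[[k]], samples[[k]]$mask), 0)
  confs <- lapply(seq_along(samples), function(k)
    pixel_confusion(binarize_prediction(preds[[k]], threshold),
                    samples[[k]]$mask))
  pooled <- sum_confusions(confs)
  m <- compute_metrics(pooled)
  acc <- (pooled$TP + pooled$TN) /
    (pooled$TP + pooled$TN + pooled$FP + pooled$FN)
  list(loss = mean(losses), metrics = m, pooled = pooled, accuracy = acc,
       preds = preds, confs = confs)
}

#' Train a Connected-SegNets model
#'
#' Mini-batch Adam on the soft IoU loss with per-epoch validation,
#' early stopping on validation loss, and checkpoint-on-best (the best
#' weights are restored into the returned model).  Seed-deterministic:
#' shuffling is fixed by `config$seed`.
#'
#' @param model A [build_architecture()] model (modified in place and
#'   returned).
#' @param train_samples,val_samples Non-empty lists of samples, each a list
#'   with `image` and `mask` matrices sized to the model input.
#' @param config A [train_config()].
#' @param checkpoint_path Optional file; when given, the best weights are
#'   also saved there at every improvement.
#' @return List of class `train_result`: `model`, `history` (one row per
#'   epoch: losses, validation Dice/IoU, pixel accuracy), `best_epoch`,
#'   `early_stop` (final state), `config`.
#' @export
train_segnet <- function(model, train_samples, val_samples,
                         config = train_config(), checkpoint_path = NULL) {
  if (length(train_samples) == 0L || length(val_samples) == 0L)
    csn_config_error("training and validation sets must be non-empty")
  state <- early_stop_state(config$patience)
  history <- list()
  best_weights <- NULL
  best_epoch <- NA_integer_
  t_adam <- 0L
  with_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(length(train_samples))
      ep_loss <- 0; nb <- 0L
      i <- 1L
      while (i <= length(ord)) {
        j <- min(i + config$batch_size - 1L, length(ord))
        sel <- ord[i:j]
        x <- stack_batch(lapply(train_samples[sel], `[[`, "image"))
        g <- stack_batch(lapply(train_samples[sel], `[[`, "mask"))
        fw <- segnet_forward(model, x, training = TRUE)
        if (!all(is.finite(fw$pred)))
          csn_data_error(sprintf(
            "non-finite activations in epoch %d; training aborted (best checkpoint kept)",
            epoch))
        lg <- batch_loss_grad(fw$pred, g)
        segnet_backward(model, fw$ctx, lg$grad)
        t_adam <- t_adam + 1L
        adam_update_model(model, config$learning_rate, t_adam)
        ep_loss <- ep_loss + lg$loss
        nb <- nb + 1L
        i <- j + 1L
      }
      ev <- eval_pass(model, val_samples, config$batch_size, config$threshold)
      state <- early_stop_update(state, ev$loss)
      improved <- state$repeats == 0L
      if (improved) {
        best_weights <- model_weights(model)
        best_epoch <- epoch
        if (!is.null(checkpoint_path)) save_checkpoint(model, checkpoint_path)
      }
      history[[epoch]] <- data.frame(
        epoch = epoch, train_loss = ep_loss / nb, val_loss = ev$loss,
        val_dice = ev$metrics$dice, val_iou = ev$metrics$iou,
        val_accuracy = ev$accuracy, improved = improved)
      if (config$verbose)
        message(sprintf(
          "epoch %3d  train %.4f  val %.4f  dice %.4f  iou %.4f%s",
          epoch, ep_loss / nb, ev$loss, ev$metrics$dice, ev$metrics$iou,
          if (improved) "  *" else ""))
      if (state$stopped) break
    }
  })
  if (!is.null(best_weights)) set_model_weights(model, best_weights)
  history <- do.call(rbind, history)
  attr(history, "hyperparameters") <- list(
    optimizer = "adam", learning_rate = config$learning_rate,
    batch_size = config$batch_size, loss = "soft_iou",
    patience = config$patience, seed = config$seed)
  structure(list(model = model, history = history, best_epoch = best_epoch,
                 early_stop = state, config = config),
            class = "train_result")
}

#' Evaluate a trained model on a test set
#'
#' @param model A trained `segnet_model`.
#' @param test_samples Non-empty list of samples (`image` + `mask`).
#' @param threshold Binarization threshold (default 0.5).
#' @param batch_size Forward batch size.
#' @return List of class `eval_result`: `per_sample` (data frame of
#'   per-sample precision/recall/Dice/IoU), `aggregate` (metrics of the
#'   pixel-pooled confusion), `pooled_confusion`, `normalized_confusion`
#'   (2 x 2 percent table), `mean_dice`, `mean_iou`.
#' @export
evaluate_segnet <- function(model, test_samples, threshold = 0.5,
                            batch_size = 4L) {
  if (length(test_samples) == 0L) csn_config_error("test set is empty")
  ev <- eval_pass(model, test_samples, batch_size, threshold)
  per <- do.call(rbind, lapply(seq_along(test_samples), function(k) {
    m <- compute_metrics(ev$confs[[k]])
    data.frame(sample = k,
               source_id = test_samples[[k]]$source_id %||% NA_character_,
               precision = m$precision, recall = m$recall, dice = m$dice,
               iou = m$iou)
  }))
  structure(list(per_sample = per,
                 aggregate = ev$metrics,
                 pooled_confusion = ev$pooled,
                 normalized_confusion = normalized_confusion_report(ev$pooled),
                 mean_dice = mean(per$dice), mean_iou = mean(per$iou)),
            class = "eval_result")
}
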