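# Soft IoU training loss and pixel-level evaluation metrics
# (precision, recall, Dice, IoU) with normalized confusion reporting.

#' Differentiable (soft) IoU loss
#'
#' `1 - (sum(p * g) + eps) / (sum(p) + sum(g) - sum(p * g) + eps)`, the
#' standard differentiable surrogate of `1 - IoU` used to train the
#' segmentation network.  For binary predictions it equals `1 - IoU`
#' exactly in the `eps -> 0` limit, and it is 0 iff a binary prediction
#' matches the target.
#'
#' @param pred Numeric grid (any shape) with values in `[0, 1]`.
#' @param target Binary grid of the same shape.
#' @param epsilon Stabilizer, default `1e-6`.
#' @return Scalar loss in `[0, 1]`.
#' @examples
#' soft_iou_loss(c(1, 1, 0, 0), c(0, 1, 1, 0))  # intersection 1, union 3 -> 2/3
#' @export
soft_iou_loss <- function(pred, target, epsilon = 1e-6) {
  if (!identical(dim(pred) %||% length(pred), dim(target) %||% length(target)))
    csn_error("pred and target shapes differ", "csn_shape_error")
  inter <- sum(pred * target)
  union <- sum(pred) + sum(target) - inter
  1 - (inter + epsilon) / (union + epsilon)
}

# gradient of soft_iou_loss with respect to pred (same shape as pred)
soft_iou_loss_grad <- function(pred, target, epsilon = 1e-6) {
  inter <- sum(pred * target)
  union <- sum(pred) + sum(target) - inter
  -(target * (union + epsilon) - (inter + epsilon) * (1 - target)) /
    (union + epsilon)^2
}

#' Pixel-level confusion counts
#'
#' Standard convention: TP are pixels predicted tumor that are tumor in the
#' ground truth, FP predicted tumor but background, FN missed tumor pixels,
#' TN correctly predicted background.
#'
#' @param pred_binary,target Binary grids of equal shape.
#' @return Object of class `pixel_confusion`: list with integer counts
#'   `TP`, `FP`, `FN`, `TN` summing to the number of pixels.
#' @export
pixel_confusion <- function(pred_binary, target) {
  if (!identical(dim(pred_binary) %||% length(pred_binary),
                 dim(target) %||% length(target)))
    csn_error("pred and target shapes differ", "csn_shape_error")
  if (!is_binary(pred_binary) || !is_binary(target))
    csn_data_error("pixel_confusion requires binary inputs")
  p <- as.logical(pred_binary); g <- as.logical(target)
  structure(list(TP = sum(p & g), FP = sum(p & !g),
                 FN = sum(!p & g), TN = sum(!p & !g)),
            class = "pixel_confusion")
}

# elementwise sum of confusion objects (pixel-pooled aggregation)
sum_confusions <- function(confs) {
  out <- list(TP = 0, FP = 0, FN = 0, TN = 0)
  for (cf in confs) for (k in names(out)) out[[k]] <- out[[k]] + cf[[k]]
  structure(out, class = "pixel_confusion")
}

#' Segmentation metrics from confusion counts
#'
#' Precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, Dice
#' `2 P R / (P + R) = 2TP/(2TP+FP+FN)` and IoU (Jaccard)
#' `TP/(TP+FP+FN)`, all as fractions in `[0, 1]`.  When prediction and
#' ground truth are both empty (`TP = FP = FN = 0`) all metrics are 1 by
#' convention (perfect agreement on "no tumor").
#'
#' @param conf A [pixel_confusion()].
#' @return List of class `seg_metrics` with `precision`, `recall`, `dice`,
#'   `iou`.
#' @examples
#' compute_metrics(pixel_confusion(c(1, 1, 1, 1, 0), c(1, 1, 1, 0, 1)))
#' @export
compute_metrics <- function(conf) {
  counts <- unlist(conf[c("TP", "FP", "FN", "TN")])
  if (any(counts < 0)) csn_data_error("negative confusion counts")
  TP <- conf$TP; FP <- conf$FP; FN <- conf$FN
  if (TP + FP + FN == 0) {
    m <- list(precision = 1, recall = 1, dice = 1, iou = 1)
  } else {
    m <- list(precision = if (TP + FP > 0) TP / (TP + FP) else 0,
              recall = if (TP + FN > 0) TP / (TP + FN) else 0,
              dice = 2 * TP / (2 * TP + FP + FN),
              iou = TP / (TP + FP + FN))
  }
  structure(m, class = "seg_metrics")
}

#' Normalized 2 x 2 confusion table (percent)
#'
#' Rates normalized per ground-truth class, matching the usual reporting of
#' segmentation confusion matrices: `TP% = TP/(TP+FN)`,
#' `FN% = FN/(TP+FN)`, `FP% = FP/(TN+FP)`, `TN% = TN/(TN+FP)`; each class
#' row sums to 100.
#'
#' @param conf A [pixel_confusion()] with at least one pixel in each
#'   ground-truth class.
#' @return 2 x 2 numeric matrix of percentages, rows
#'   `c("Tumor", "Non-Tumor")` (prediction side ordering of the cells as
#'   `[[TP, FN], [FP, TN]]`).
#' @export
normalized_confusion_report <- function(conf) {
  if (conf$TP + conf$FN == 0 || conf$TN + conf$FP == 0)
    csn_data_error("a ground-truth class is empty; rates undefined")
  pos <- conf$TP + conf$FN
  neg <- conf$TN + conf$FP
  matrix(100 * c(conf$TP / pos, conf$FP / neg, conf$FN / pos, conf$TN / neg),
         2, 2, dimnames = list(c("Tumor", "Non-Tumor"),
                               c("Tumor", "Non-Tumor")))
}

#' Binarize a soft prediction
#'
#' @param pred Numeric grid in `[0, 1]`.
#' @param threshold Decision threshold, default 0.5.
#' @export
binarize_prediction <- function(pred, threshold = 0.5) (pred >= threshold) * 1

#' Write metrics as JSON (percent, 2 decimals)
#'
#' @param metrics A `seg_metrics` object.
#' @param path Output file.
#' @export
write_metrics_json <- function(metrics, path) {
  out <- lapply(metrics, function(v) round(100 * v, 2))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
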