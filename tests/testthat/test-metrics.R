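# Soft IoU loss and the confusion-matrix metrics.

test_that("soft IoU loss matches hand-counted set arithmetic", {
  expect_equal(soft_iou_loss(c(1, 1, 0, 0), c(0, 1, 1, 0)), 2 / 3,
               tolerance = 1e-5)
  g <- random_binary_mask(8, 1)
  expect_equal(soft_iou_loss(g, g), 0, tolerance = 1e-6)
  # disjoint nonempty sets: loss = 1 - eps / (|p| + |g| + eps)
  p <- matrix(0, 4, 4); p[1, 1:2] <- 1
  g <- matrix(0, 4, 4); g[3, 1:3] <- 1
  eps <- 1e-6
  expect_equal(soft_iou_loss(p, g, eps), 1 - eps / (5 + eps), tolerance = 1e-12)
  expect_error(soft_iou_loss(matrix(0, 2, 2), matrix(0, 2, 3)),
               class = "csn_shape_error")
})

test_that("soft IoU loss gradient matches finite differences", {
  with_test_seed(5, {
    p <- matrix(runif(16, 0.05, 0.95), 4)
    g <- matrix((runif(16) > 0.5) * 1, 4)
  })
  an <- ConnSegNets:::soft_iou_loss_grad(p, g)
  eps <- 1e-7
  for (i in c(1, 7, 16)) {
    p1 <- p; p1[i] <- p1[i] + eps
    p0 <- p; p0[i] <- p0[i] - eps
    expect_equal(an[i], (soft_iou_loss(p1, g) - soft_iou_loss(p0, g)) / (2 * eps),
                 tolerance = 1e-4)
  }
})

test_that("pixel confusion equals an exhaustive per-pixel tally", {
  tally <- function(p, g) {
    counts <- c(TP = 0, FP = 0, FN = 0, TN = 0)
    for (i in seq_along(p)) {
      k <- if (p[i] == 1 && g[i] == 1) "TP" else if (p[i] == 1) "FP"
           else if (g[i] == 1) "FN" else "TN"
      counts[k] <- counts[k] + 1
    }
    counts
  }
  for (seed in 1:5) {
    p <- random_binary_mask(16, seed)
    g <- random_binary_mask(16, seed + 100)
    cf <- pixel_confusion(p, g)
    expect_equal(unlist(cf[c("TP", "FP", "FN", "TN")]),
                 tally(p, g)[c("TP", "FP", "FN", "TN")])
    expect_equal(cf$TP + cf$FP + cf$FN + cf$TN, 256)
  }
  expect_error(pixel_confusion(matrix(0.5, 2, 2), matrix(0, 2, 2)),
               class = "csn_data_error")
})

test_that("metrics follow the precision/recall/Dice/IoU formulas", {
  m <- compute_metrics(structure(list(TP = 3, FP = 1, FN = 1, TN = 11),
                                 class = "pixel_confusion"))
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.75)
  expect_equal(m$dice, 0.75)
  expect_equal(m$iou, 0.6)

  perfect <- compute_metrics(structure(list(TP = 9, FP = 0, FN = 0, TN = 0),
                                       class = "pixel_confusion"))
  expect_true(all(unlist(perfect) == 1))
  # both masks empty: perfect agreement by convention
  empty <- compute_metrics(structure(list(TP = 0, FP = 0, FN = 0, TN = 4),
                                     class = "pixel_confusion"))
  expect_equal(empty$dice, 1)
  expect_equal(empty$iou, 1)
})

test_that("dice/iou identity, ordering and scale invariance hold", {
  with_test_seed(8, {
    for (i in 1:200) {
      cf <- structure(as.list(c(TP = sample(0:50, 1), FP = sample(0:50, 1),
                                FN = sample(0:50, 1), TN = sample(0:50, 1))),
                      class = "pixel_confusion")
      m <- compute_metrics(cf)
      if (m$iou > 0)
        expect_equal(m$dice, 2 * m$iou / (1 + m$iou), tolerance = 1e-12)
      expect_gte(m$dice, m$iou)
      mk <- compute_metrics(structure(lapply(cf, `*`, 7),
                                      class = "pixel_confusion"))
      expect_equal(unlist(m), unlist(mk), tolerance = 1e-12)
    }
  })
})

test_that("normalized confusion reports per-ground-truth-class percentages", {
  cf <- structure(list(TP = 96, FN = 4, FP = 12, TN = 88),
                  class = "pixel_confusion")
  tab <- normalized_confusion_report(cf)
  expect_equal(unname(tab), matrix(c(96, 12, 4, 88), 2, 2))
  expect_equal(rowSums(tab), c(Tumor = 100, `Non-Tumor` = 100))

  perfect <- structure(list(TP = 5, FN = 0, FP = 0, TN = 15),
                       class = "pixel_confusion")
  expect_equal(unname(normalized_confusion_report(perfect)),
               matrix(c(100, 0, 0, 100), 2, 2))
  expect_error(normalized_confusion_report(
    structure(list(TP = 0, FN = 0, FP = 2, TN = 2),
              class = "pixel_confusion")),
    class = "csn_data_error")
})

test_that("binarization and JSON metric export behave", {
  p <- matrix(c(0.2, 0.5, 0.7, 0.49), 2)
  expect_equal(binarize_prediction(p), matrix(c(0, 1, 1, 0), 2))
  f <- withr::local_tempfile(fileext = ".json")
  write_metrics_json(structure(list(precision = 0.912, recall = 1,
                                    dice = 0.9536, iou = 0.9121),
                               class = "seg_metrics"), f)
  got <- jsonlite::read_json(f)
  expect_equal(got$dice, 95.36)
})
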