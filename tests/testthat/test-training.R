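# Early stopping and the training/evaluation loop.

test_that("early stopping tracks best loss and consecutive non-improvements", {
  st <- early_stop_state(patience = 20)
  st <- early_stop_update(st, 0.5)
  expect_equal(st$best, 0.5)
  expect_equal(st$repeats, 0L)
  expect_false(st$stopped)

  st <- early_stop_update(st, 0.4)   # strict improvement resets
  expect_equal(st$best, 0.4)
  expect_equal(st$repeats, 0L)

  st <- early_stop_update(st, 0.4)   # tie counts as non-improving
  expect_equal(st$repeats, 1L)
  expect_equal(st$best, 0.4)
})

test_that("a flat loss stream stops after exactly patience + 1 updates", {
  st <- early_stop_state(patience = 3)
  st <- early_stop_update(st, 1.0)   # first call sets the best
  for (k in 1:3) {
    st <- early_stop_update(st, 1.0)
    expect_false(st$stopped)
  }
  st <- early_stop_update(st, 1.0)   # 4th non-improving update
  expect_true(st$stopped)

  # best score is non-increasing over arbitrary streams
  st <- early_stop_state(patience = 5)
  with_test_seed(3, losses <- runif(30))
  bests <- numeric(0)
  for (l in losses) {
    st <- early_stop_update(st, l)
    bests <- c(bests, st$best)
  }
  expect_true(all(diff(bests) <= 0))
  expect_error(early_stop_update(early_stop_state(), NaN),
               class = "csn_data_error")
})

test_that("a strictly decreasing loss stream never triggers the stop", {
  st <- early_stop_state(patience = 2)
  for (l in seq(1, 0.1, by = -0.05)) st <- early_stop_update(st, l)
  expect_false(st$stopped)
  expect_equal(st$repeats, 0L)
})

test_that("training respects the epoch budget and logs hyperparameters", {
  samples <- micro_samples(8, seed = 40)
  model <- micro_model(seed = 1)
  cfg <- train_config(learning_rate = 1e-3, max_epochs = 1, seed = 2)
  res <- train_segnet(model, samples[1:6], samples[7:8], cfg)
  expect_equal(nrow(res$history), 1)
  hp <- attr(res$history, "hyperparameters")
  expect_equal(hp$learning_rate, 1e-3)
  expect_equal(hp$batch_size, 4L)
  expect_equal(hp$optimizer, "adam")
  expect_error(train_segnet(model, list(), samples, cfg),
               class = "csn_config_error")
})

test_that("training is reproducible under a fixed seed", {
  samples <- micro_samples(8, seed = 50)
  run <- function() {
    model <- micro_model(seed = 3)
    train_segnet(model, samples[1:6], samples[7:8],
                 train_config(learning_rate = 1e-3, max_epochs = 2,
                              seed = 4))$history
  }
  expect_equal(run(), run(), tolerance = 1e-12)
})

test_that("a few epochs reduce the training loss on phantom data", {
  # majority over seeds: descent from a random initialization
  wins <- 0
  for (seed in 1:3) {
    samples <- micro_samples(24, seed = 60 + 100 * seed)
    model <- micro_model(seed = seed)
    res <- train_segnet(model, samples[1:20], samples[21:24],
                        train_config(learning_rate = 1e-3, max_epochs = 2,
                                     seed = seed))
    h <- res$history$train_loss
    if (tail(h, 1) < h[1]) wins <- wins + 1
  }
  expect_gte(wins, 2)
})

test_that("evaluation pools confusions over samples consistently", {
  samples <- micro_samples(6, seed = 70)
  model <- micro_model(seed = 5)
  ev <- evaluate_segnet(model, samples, threshold = 0.5)
  expect_equal(nrow(ev$per_sample), 6)
  # aggregate metrics equal metrics of the summed per-sample confusions
  preds <- ConnSegNets:::predict_samples(model, samples)
  confs <- lapply(seq_along(samples), function(k)
    pixel_confusion(binarize_prediction(preds[[k]], 0.5),
                    samples[[k]]$mask))
  pooled <- ConnSegNets:::sum_confusions(confs)
  expect_equal(unlist(ev$aggregate), unlist(compute_metrics(pooled)))
  expect_equal(rowSums(ev$normalized_confusion),
               c(Tumor = 100, `Non-Tumor` = 100))

  # a threshold no prediction can reach gives all-background masks: recall 0
  ev0 <- evaluate_segnet(model, samples, threshold = 1.5)
  expect_equal(ev0$aggregate$recall, 0)
  expect_error(evaluate_segnet(model, list()), class = "csn_config_error")
})
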