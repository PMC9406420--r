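# Graph assembly: shapes, stage counts, determinism, checkpoints.

test_that("width-scaled models realize the scaled layer schedule exactly", {
  # recompute the schedule under the scaling and assert per-layer agreement
  for (cfg in list(model_config(input_size = 32, width_multiplier = 1 / 16),
                   model_config(input_size = 64, width_multiplier = 1 / 8))) {
    model <- build_architecture(cfg)
    sch <- connected_segnet_schedule(cfg)
    got <- realized_layer_shapes(model)
    ref <- sch[match(got$no, sch$no), ]
    expect_equal(got$out_h, ref$out_h)
    expect_equal(got$out_w, ref$out_w)
    expect_equal(got$out_c, ref$out_c)
  }
})

test_that("the deepest encoder features sit at 1/32 spatial scale", {
  model <- micro_model()
  fw <- segnet_forward(model, matrix(0.5, 32, 32))
  ch <- model$config$channel_schedule
  expect_equal(fw$shapes[["s1e_pool5"]], c(1L, 1L, ch[5], 1L))
  expect_equal(fw$shapes[["s2e_pool5"]], c(1L, 1L, ch[5], 1L))
  expect_equal(fw$shapes[["out"]], c(32L, 32L, 1L, 1L))
})

test_that("stage counts: 5 pools/unpools per SegNet, 5 concats in the second", {
  st <- count_stages(micro_model())
  expect_equal(st$segnet1, c(pools = 5L, unpools = 5L, concats = 0L))
  expect_equal(st$segnet2, c(pools = 5L, unpools = 5L, concats = 5L))

  single <- build_architecture(model_config(input_size = 32,
                                            width_multiplier = 1 / 16,
                                            n_segnets = 1))
  st1 <- count_stages(single)
  expect_equal(st1$segnet1, c(pools = 5L, unpools = 5L, concats = 0L))
  expect_null(st1$segnet2)
  expect_equal(dim(segnet_forward(single, matrix(0.5, 32, 32))$pred),
               c(32L, 32L, 1L, 1L))
})

test_that("inference is deterministic, batched and range-bounded", {
  model <- micro_model()
  with_test_seed(11, x <- array(runif(32 * 32 * 4), c(32, 32, 1, 4)))
  p1 <- segnet_forward(model, x)$pred
  p2 <- segnet_forward(model, x)$pred
  expect_identical(p1, p2)
  expect_equal(dim(p1), c(32L, 32L, 1L, 4L))
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_true(all(is.finite(segnet_forward(model,
    array(0, c(32, 32, 1, 2)))$pred)))
})

test_that("invalid configurations and input sizes are rejected", {
  expect_error(model_config(input_size = 48), class = "csn_config_error")
  expect_error(model_config(input_size = 0), class = "csn_config_error")
  model <- micro_model()
  expect_error(segnet_forward(model, matrix(0, 64, 64)),
               class = "csn_shape_error")
})

test_that("initialization is seed-deterministic and seed-sensitive", {
  m1 <- micro_model(seed = 5)
  m2 <- micro_model(seed = 5)
  m3 <- micro_model(seed = 6)
  expect_identical(m1$nodes$s1e_conv1$units[[1]]$W,
                   m2$nodes$s1e_conv1$units[[1]]$W)
  expect_false(identical(m1$nodes$s1e_conv1$units[[1]]$W,
                         m3$nodes$s1e_conv1$units[[1]]$W))
})

test_that("checkpoints round-trip weights and predictions", {
  model <- micro_model(seed = 9)
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(model, f)
  restored <- load_checkpoint(f)
  with_test_seed(12, x <- matrix(runif(32 * 32), 32))
  expect_identical(segnet_forward(model, x)$pred,
                   segnet_forward(restored, x)$pred)
  expect_error(load_checkpoint(file.path(tempdir(), "absent.rds")),
               class = "csn_dependency_error")
})

test_that("the model summary mirrors the 54-row layer table", {
  s <- summary(micro_model())
  expect_equal(nrow(s), 54)
  expect_equal(s$name[c(1, 2, 26, 53, 54)],
               c("Input", "Conv1", "Conv14", "Conv27", "Output"))
  expect_equal(s$dilation[53], 3)
  sch <- connected_segnet_schedule(model_config())
  expect_true(sch$corrected[sch$no == 34])
  expect_equal(sum(sch$corrected), 1)
})
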