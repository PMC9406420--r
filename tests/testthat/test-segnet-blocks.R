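# Layer primitives: convolution, pooling with indices, unpooling,
# activations, batch normalization.

naive_conv <- function(x, w, b, dil = 1) {
  H <- dim(x)[1]; W <- dim(x)[2]; Ci <- dim(x)[3]; N <- dim(x)[4]
  kh <- dim(w)[1]; kw <- dim(w)[2]; Co <- dim(w)[4]
  ph <- dil * (kh - 1) %/% 2; pw <- dil * (kw - 1) %/% 2
  y <- array(0, c(H, W, Co, N))
  for (n in 1:N) for (co in 1:Co) for (h in 1:H) for (wd in 1:W) {
    s <- b[co]
    for (ci in 1:Ci) for (ki in 1:kh) for (kj in 1:kw) {
      hh <- h + dil * (ki - 1) - ph
      ww <- wd + dil * (kj - 1) - pw
      if (hh >= 1 && hh <= H && ww >= 1 && ww <= W)
        s <- s + x[hh, ww, ci, n] * w[ki, kj, ci, co]
    }
    y[h, wd, co, n] <- s
  }
  y
}

test_that("same-padding convolution matches a direct sliding-window oracle", {
  with_test_seed(1, {
    x <- array(rnorm(6 * 6 * 2 * 2), c(6, 6, 2, 2))
    w <- array(rnorm(3 * 3 * 2 * 4), c(3, 3, 2, 4))
    b <- rnorm(4)
  })
  expect_equal(nn_conv2d(x, w, b), naive_conv(x, w, b), tolerance = 1e-12)
  # dilation 1 is ordinary convolution; dilation 3 matches the oracle too
  expect_equal(nn_conv2d(x, w, b, dilation = 3), naive_conv(x, w, b, 3),
               tolerance = 1e-12)
  expect_error(nn_conv2d(x, array(0, c(3, 3, 5, 4)), numeric(4)))
})

test_that("a dilated kernel's impulse response has taps spaced by the rate", {
  w <- array(0, c(3, 3, 1, 1))
  w[, , 1, 1] <- matrix(1:9, 3, 3)
  x <- array(0, c(15, 15, 1, 1))
  x[8, 8, 1, 1] <- 1
  y <- nn_conv2d(x, w, numeric(1), dilation = 3)
  nz <- which(y[, , 1, 1] != 0, arr.ind = TRUE)
  # cross-correlation places tap (ki, kj) at the mirrored offset
  expect_setequal(nz[, 1], c(5, 8, 11))
  expect_setequal(nz[, 2], c(5, 8, 11))
  expect_equal(y[8, 8, 1, 1], w[2, 2, 1, 1])
  expect_equal(y[5, 5, 1, 1], w[3, 3, 1, 1])
})

test_that("2x2 max pooling records row-major argmax indices", {
  m <- matrix(1:16, 4, 4, byrow = TRUE)  # values 1..16 row-major
  pl <- max_pool_indices(m)
  expect_equal(pl$y[, , 1, 1], matrix(c(6, 14, 8, 16), 2, 2))
  expect_true(all(pl$idx == 3L))  # bottom-right of each window

  const <- max_pool_indices(matrix(5, 4, 4))
  expect_true(all(const$y == 5))
  expect_true(all(const$idx == 0L))  # ties keep the first cell

  big <- max_pool_indices(array(0, c(8, 6, 3, 2)))
  expect_identical(dim(big$y), c(4L, 3L, 3L, 2L))
  expect_error(max_pool_indices(matrix(0, 5, 4)), class = "csn_shape_error")
})

test_that("unpooling places one value per window and round-trips", {
  with_test_seed(2, x <- array(sample(1:1000, 8 * 8 * 3 * 2), c(8, 8, 3, 2)))
  pl <- max_pool_indices(x)
  up <- unpool_indices(pl$y, pl$idx)
  expect_identical(dim(up), dim(x))
  # distinct values: exactly H*W/4 nonzeros per channel, at argmax cells
  expect_equal(sum(up != 0), 8 * 8 / 4 * 3 * 2)
  expect_true(all(up[up != 0] %in% x))
  # pool(unpool(p, idx)) recovers p exactly
  expect_equal(max_pool_indices(up)$y, pl$y)
  # and every placed maximum sits where x attains it
  expect_true(all((up == x | up == 0)))
  expect_error(unpool_indices(pl$y, pl$idx[, , 1:2, ]), class = "csn_shape_error")
})

test_that("advanced ReLU clamps to [0, 1], idempotently and monotonely", {
  expect_equal(advanced_relu(-0.5), 0)
  expect_equal(advanced_relu(0.3), 0.3)
  expect_equal(advanced_relu(2.7), 1)
  v <- seq(-2, 3, by = 0.1)
  expect_equal(advanced_relu(advanced_relu(v)), advanced_relu(v))
  expect_true(all(diff(advanced_relu(v)) >= 0))
  # C++ fast path agrees with the reference definition
  with_test_seed(3, z <- array(rnorm(100, sd = 2), c(5, 5, 2, 2)))
  expect_equal(ConnSegNets:::act_forward(z, "advanced_relu"),
               pmin(pmax(z, 0), 1))
})

test_that("conv block preserves spatial dims and sets channels to filters", {
  with_test_seed(4, x <- array(runif(16 * 16 * 3), c(16, 16, 3, 1)))
  u1 <- ConnSegNets:::new_conv_unit(3, 3, 3, 5, TRUE)
  u2 <- ConnSegNets:::new_conv_unit(3, 3, 5, 5, TRUE)
  y <- ConnSegNets:::conv_unit_forward(x, u1, "relu", 1L, "act_bn", FALSE)$y
  y <- ConnSegNets:::conv_unit_forward(y, u2, "relu", 1L, "act_bn", FALSE)$y
  expect_identical(dim(y), c(16L, 16L, 5L, 1L))
  # zero input, zero bias: ReLU output is all zero before the BN shift
  z <- nn_conv2d(array(0, c(8, 8, 3, 1)), u1$W, u1$b)
  expect_true(all(ConnSegNets:::act_forward(z, "relu") == 0))
})

test_that("conv+ReLU+BN unit gradients match finite differences", {
  with_test_seed(6, {
    x <- array(rnorm(8 * 8 * 2 * 3), c(8, 8, 2, 3))
    g <- array(rnorm(8 * 8 * 4 * 3), c(8, 8, 4, 3))
  })
  u <- ConnSegNets:::new_conv_unit(3, 3, 2, 4, TRUE)
  fwd <- function() ConnSegNets:::conv_unit_forward(x, u, "relu", 1L,
                                                    "act_bn", TRUE)
  loss <- function() sum(fwd()$y * g)
  f <- fwd()
  dx <- ConnSegNets:::conv_unit_backward(g, u, f$cache, "relu", 1L, "act_bn")
  eps <- 1e-6
  numgrad <- function(set) {
    set(eps); l1 <- loss(); set(-2 * eps); l0 <- loss(); set(eps)
    (l1 - l0) / (2 * eps)
  }
  expect_equal(u$dW[2, 1, 1, 3],
               numgrad(function(e) u$W[2, 1, 1, 3] <- u$W[2, 1, 1, 3] + e),
               tolerance = 1e-4)
  expect_equal(u$db[3],
               numgrad(function(e) u$b[3] <- u$b[3] + e), tolerance = 1e-4)
  expect_equal(u$dgamma[2],
               numgrad(function(e) u$gamma[2] <- u$gamma[2] + e),
               tolerance = 1e-4)
  expect_equal(u$dbeta[4],
               numgrad(function(e) u$beta[4] <- u$beta[4] + e),
               tolerance = 1e-4)
  expect_equal(dx[4, 5, 1, 2],
               numgrad(function(e) x[4, 5, 1, 2] <<- x[4, 5, 1, 2] + e),
               tolerance = 1e-4)
})

test_that("batch norm uses running statistics at inference", {
  with_test_seed(7, x <- array(rnorm(8 * 8 * 2 * 4, mean = 3), c(8, 8, 2, 4)))
  u <- ConnSegNets:::new_conv_unit(3, 3, 2, 2, TRUE)
  for (i in 1:200)
    ConnSegNets:::conv_unit_forward(x, u, "relu", 1L, "act_bn", TRUE)
  y1 <- ConnSegNets:::conv_unit_forward(x, u, "relu", 1L, "act_bn", FALSE)$y
  y2 <- ConnSegNets:::conv_unit_forward(x, u, "relu", 1L, "act_bn", FALSE)$y
  expect_identical(y1, y2)
  # after converging running stats on a fixed batch, the two modes agree
  # (absolute scale: activations are O(1))
  yt <- ConnSegNets:::conv_unit_forward(x, u, "relu", 1L, "act_bn", TRUE)$y
  expect_lt(max(abs(y1 - yt)), 0.05)
})
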