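# Layer primitives: convolution (with dilation), max pooling with recorded
# indices, index-driven unpooling, batch normalization, activations and the
# Adam update.  Feature maps are (H, W, C, N) arrays.

#' 2-D convolution with same-padding
#'
#' @param x `(H, W, C, N)` array (a matrix or `(H, W, C)` array is promoted).
#' @param w `(kh, kw, Cin, Cout)` weight array.
#' @param b Length-`Cout` bias vector.
#' @param dilation Integer dilation rate >= 1 (kernel taps spaced
#'   `dilation` pixels apart; spatial dimensions are always preserved).
#' @return `(H, W, Cout, N)` array.
#' @export
nn_conv2d <- function(x, w, b = numeric(dim(w)[4]), dilation = 1L) {
  x <- as_tensor(x)
  if (dilation < 1) csn_config_error("dilation must be >= 1")
  cpp_conv2d_forward(x, dim(x), w, dim(w), b, as.integer(dilation))
}

nn_conv2d_backward <- function(x, w, dy, dilation = 1L) {
  cpp_conv2d_backward(x, dim(x), w, dim(w), dy, as.integer(dilation))
}

#' 2 x 2 max pooling with recorded argmax indices
#'
#' Halves both spatial dimensions; each output value is the maximum of its
#' 2 x 2 window and `idx` records the argmax cell within the window
#' (row-major window order, ties broken by first occurrence) for later
#' index-driven unpooling.
#'
#' @param x `(H, W, C, N)` array with even `H` and `W`.
#' @return List with `y` (`(H/2, W/2, C, N)`) and integer `idx` of the same
#'   shape with values in `0:3`.
#' @export
max_pool_indices <- function(x) {
  x <- as_tensor(x)
  d <- dim(x)
  if (d[1] %% 2L || d[2] %% 2L)
    csn_error(sprintf("max pooling needs even spatial dims, got %dx%d", d[1], d[2]),
              "csn_shape_error")
  cpp_maxpool(x, d)
}

#' Index-driven unpooling (SegNet upsampling)
#'
#' Doubles both spatial dimensions, placing each pooled value at the
#' position recorded by [max_pool_indices()] and zeros elsewhere.
#'
#' @param pooled `(H, W, C, N)` array.
#' @param idx Integer index array of identical shape (from
#'   [max_pool_indices()]).
#' @return `(2H, 2W, C, N)` array.
#' @export
unpool_indices <- function(pooled, idx) {
  pooled <- as_tensor(pooled)
  if (!identical(dim(pooled), dim(idx)))
    csn_error("pooled values and indices have different shapes", "csn_shape_error")
  cpp_index_scatter(pooled, dim(pooled), idx)
}

max_pool_backward <- function(dy, idx) cpp_index_scatter(dy, dim(dy), idx)
unpool_backward <- function(dy, idx) cpp_index_gather(dy, dim(dy), idx)

#' Capped rectified linear activation
#'
#' Elementwise `min(max(x, 0), 1)`: a ReLU whose output is additionally
#' limited to 1, used before the network's output convolution so activations
#' stay in the mask intensity range.  Idempotent and monotone.
#'
#' @param x Numeric array.
#' @export
advanced_relu <- function(x) pmin(pmax(x, 0), 1)

relu <- function(x) pmax(x, 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

act_forward <- function(z, act) {
  switch(act,
         relu = cpp_act_forward(z, 0L),
         advanced_relu = cpp_act_forward(z, 1L),
         sigmoid = sigmoid(z),
         linear = z,
         csn_config_error(sprintf("unknown activation '%s'", act)))
}

# derivative as a function of pre-activation z (and output a for sigmoid)
act_backward <- function(da, z, a, act) {
  switch(act,
         relu = cpp_act_backward(da, z, 0L),
         advanced_relu = cpp_act_backward(da, z, 1L),
         sigmoid = da * a * (1 - a),
         linear = da)
}

# ---- batch normalization (per channel over H, W and batch) ----
# thin wrappers over the C++ kernels; `bn_forward` returns the batch (or
# running) statistics so the backward pass can differentiate through them

bn_forward <- function(x, gamma, beta, batch_stats, rmean, rvar, eps = 1e-5) {
  cpp_bn_forward(x, dim(x), gamma, beta, eps, batch_stats, rmean, rvar)
}

bn_backward <- function(x, dy, gamma, mu, var, eps = 1e-5) {
  cpp_bn_backward(x, dim(x), dy, gamma, mu, var, eps)
}

# ---- parameter initialization and Adam ----

he_init <- function(kh, kw, cin, cout) {
  array(stats::rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
        c(kh, kw, cin, cout))
}

# in-place first/second moment buffers; returns the updated parameters
adam_step <- function(p, g, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  cpp_adam_step(p, g, state$m, state$v, lr, as.integer(t), beta1, beta2, eps)
}
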