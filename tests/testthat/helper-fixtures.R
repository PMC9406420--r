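# shared fixtures: all built in code, deterministic per seed

random_binary_mask <- function(n, seed, p = 0.3) {
  with_test_seed(seed, matrix((runif(n * n) < p) * 1, n, n))
}

random_image <- function(n, seed) {
  with_test_seed(seed, matrix(runif(n * n), n, n))
}

with_test_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# smallest full-topology model: 1/16 width on 32 x 32 inputs
micro_model <- function(seed = 7, ...) {
  build_architecture(model_config(input_size = 32L, width_multiplier = 1 / 16,
                                  seed = seed, ...))
}

micro_samples <- function(n, seed, size = 32L) {
  lapply(seq_len(n), function(i) {
    p <- generate_phantom(phantom_spec(
      seed = seed + i, size = size,
      lesion_radius_range = round(size * c(0.15, 0.3))))
    list(image = p$image, mask = p$mask)
  })
}
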