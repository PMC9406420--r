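# Deterministic eight-fold rotation/flip augmentation and train/validation
# splitting.

#' The eight rotation/flip augmentation variants
#'
#' Counter-clockwise rotations by 0/90/180/270 degrees crossed with an
#' optional horizontal mirror: the dihedral group D4 acting on the pixel
#' grid.
#'
#' @return Data frame with columns `rotation` (degrees) and `flipped`.
#' @export
augmentation_variants <- function() {
  expand.grid(rotation = c(0L, 90L, 180L, 270L), flipped = c(FALSE, TRUE),
              KEEP.OUT.ATTRS = FALSE)
}

# exact 90-degree counter-clockwise rotation (grid permutation, no
# interpolation): for multiples of 90 degrees bilinear rotation reduces to
# exactly this
rot90_ccw <- function(m) {
  tm <- t(m)
  tm[rev(seq_len(nrow(tm))), , drop = FALSE]
}

flip_horizontal <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]

apply_variant <- function(m, rotation, flipped) {
  if (flipped) m <- flip_horizontal(m)
  for (i in seq_len((rotation %/% 90L) %% 4L)) m <- rot90_ccw(m)
  m
}

#' Eight-fold augmentation of one ROI sample
#'
#' Applies the identical transform jointly to image and mask for each of the
#' eight [augmentation_variants()].  Rotations are exact grid permutations,
#' so mask binarity and foreground pixel counts are preserved.
#'
#' @param sample An `roi_sample` (or any list with square `image` and `mask`
#'   matrices).
#' @return List of 8 samples; each gains `variant_rotation` and
#'   `variant_flipped` fields.
#' @export
augment_eightfold <- function(sample) {
  if (nrow(sample$image) != ncol(sample$image))
    csn_error("augmentation requires square inputs (90-degree rotations would change dimensions)",
              "csn_shape_error")
  v <- augmentation_variants()
  lapply(seq_len(nrow(v)), function(i) {
    out <- sample
    out$image <- apply_variant(sample$image, v$rotation[i], v$flipped[i])
    out$mask <- apply_variant(sample$mask, v$rotation[i], v$flipped[i])
    out$variant_rotation <- v$rotation[i]
    out$variant_flipped <- v$flipped[i]
    out
  })
}

#' Train/validation split specification
#'
#' @param train_fraction Fraction in (0, 1); the training pool receives
#'   `floor(train_fraction * N)` samples.  The default 0.8 reproduces the
#'   published augmented-split counts (576/144, 4659/1165, 947/237).
#' @param seed Shuffle seed.
#' @export
split_spec <- function(train_fraction = 0.8, seed = 42L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    csn_config_error("train_fraction must lie strictly between 0 and 1")
  structure(list(train_fraction = train_fraction, seed = as.integer(seed)),
            class = "split_spec")
}

#' Seed-deterministic train/validation split
#'
#' Shuffles the samples with the spec's seed and assigns the first
#' `floor(train_fraction * N)` to training, the remainder to validation.
#' The two parts are disjoint and exhaustive.
#'
#' @param samples List (or data frame) of at least 2 items.
#' @param spec A [split_spec()].
#' @return List with elements `train` and `validation` of the same type as
#'   the input.
#' @export
split_train_val <- function(samples, spec = split_spec()) {
  N <- if (is.data.frame(samples)) nrow(samples) else length(samples)
  if (N < 2) csn_error("need at least 2 samples to split", "csn_size_error")
  n_train <- floor(spec$train_fraction * N)
  perm <- with_seed(spec$seed, sample.int(N))
  take <- function(idx) if (is.data.frame(samples))
    samples[idx, , drop = FALSE] else samples[idx]
  list(train = take(perm[seq_len(n_train)]),
       validation = take(perm[seq.int(n_train + 1L, N)]))
}
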