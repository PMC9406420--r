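# Synthetic mammogram-phantom generator.
#
# Emulates the statistical structure the segmentation pipeline assumes:
# low-contrast blob lesions with irregular boundaries embedded in a textured
# background whose intensities occupy a compressed dynamic range (so CLAHE
# has a measurable effect), paired with exact ground-truth masks.

#' Specification of a synthetic mammographic phantom
#'
#' Describes one region-of-interest phantom: a textured background with a
#' compressed dynamic range plus `n_lesions` blob lesions of slightly higher
#' intensity, and the exact binary mask of their union.
#'
#' @param seed Integer seed; the same spec is guaranteed to produce
#'   bit-identical output.
#' @param size Pixels per side of the square image (default 256).
#' @param n_lesions Number of lesions (>= 0).
#' @param lesion_radius_range Numeric `(min, max)` nominal lesion radius in
#'   pixels; minimum must be >= 2.  Default scales with `size`
#'   (roughly 12--25% of the side).
#' @param lesion_contrast Mean intensity offset of the lesion above the
#'   background, in `[0, 0.5]`.
#' @param boundary_irregularity Dimensionless >= 0; amplitude of the
#'   low-frequency radial perturbation that deforms the lesion boundary
#'   (0 gives a circular lesion).  Values are capped at 0.9.
#' @param background_texture_scale Correlation length, in pixels, of the
#'   smoothed random field used as background texture.
#' @param noise_sd Standard deviation of the additive Gaussian pixel noise.
#' @param dynamic_range Numeric `(low, high)` inside `[0, 1]`; the background
#'   is rescaled into this compressed range (default `c(0.3, 0.7)`).
#'
#' @return An object of class `phantom_spec`.
#' @seealso [generate_phantom()], [generate_dataset()]
#' @export
phantom_spec <- function(seed = 1L,
                         size = 256L,
                         n_lesions = 1L,
                         lesion_radius_range = round(size * c(0.12, 0.25)),
                         lesion_contrast = 0.25,
                         boundary_irregularity = 0.3,
                         background_texture_scale = size / 8,
                         noise_sd = 0.02,
                         dynamic_range = c(0.3, 0.7)) {
  size <- as.integer(size)
  if (size < 8L) csn_config_error("size must be at least 8 pixels")
  if (n_lesions < 0L) csn_config_error("n_lesions must be >= 0")
  if (length(lesion_radius_range) != 2L ||
      lesion_radius_range[1] < 2 ||
      lesion_radius_range[2] < lesion_radius_range[1])
    csn_config_error("lesion_radius_range must be (min, max) with min >= 2")
  if (lesion_contrast < 0 || lesion_contrast > 0.5)
    csn_config_error("lesion_contrast must lie in [0, 0.5]")
  if (boundary_irregularity < 0)
    csn_config_error("boundary_irregularity must be >= 0")
  if (length(dynamic_range) != 2L ||
      dynamic_range[1] < 0 || dynamic_range[2] > 1 ||
      dynamic_range[1] >= dynamic_range[2])
    csn_config_error("dynamic_range must be (low, high) with 0 <= low < high <= 1")
  structure(list(seed = as.integer(seed), size = size,
                 n_lesions = as.integer(n_lesions),
                 lesion_radius_range = as.numeric(lesion_radius_range),
                 lesion_contrast = lesion_contrast,
                 boundary_irregularity = min(boundary_irregularity, 0.9),
                 background_texture_scale = background_texture_scale,
                 noise_sd = noise_sd,
                 dynamic_range = as.numeric(dynamic_range)),
            class = "phantom_spec")
}

# smooth random field: coarse white noise, bilinearly upsampled, minmax
# rescaled into the compressed dynamic range
phantom_background <- function(size, texture_scale, dynamic_range) {
  ncoarse <- max(2L, as.integer(ceiling(size / texture_scale)) + 1L)
  coarse <- matrix(stats::rnorm(ncoarse^2), ncoarse, ncoarse)
  field <- ebi_resize(coarse, size, bilinear = TRUE)
  rng <- range(field)
  span <- if (rng[2] > rng[1]) rng[2] - rng[1] else 1
  dynamic_range[1] +
    (field - rng[1]) / span * (dynamic_range[2] - dynamic_range[1])
}

# one lesion: a disk of nominal radius r whose boundary radius is modulated
# by zero-mean low-frequency harmonics, radial(theta) = r * (1 + irr * s(theta))
# with max|s| = 1, so radial stays within r * (1 -+ irr) and the enclosed
# (continuous) area is >= pi r^2.
phantom_lesion <- function(size, radius_range, irregularity) {
  r <- stats::runif(1, radius_range[1], radius_range[2])
  rmax <- r * (1 + irregularity)
  lo <- rmax + 1
  hi <- size - rmax
  if (hi <= lo) { lo <- size / 2; hi <- size / 2 }  # lesion barely fits
  cy <- stats::runif(1, lo, hi)
  cx <- stats::runif(1, lo, hi)
  kh <- 2:4
  amp <- stats::rnorm(3) / kh
  pha <- stats::runif(3, 0, 2 * pi)
  yy <- matrix(seq_len(size), size, size) - cy
  xx <- matrix(seq_len(size), size, size, byrow = TRUE) - cx
  d <- sqrt(yy^2 + xx^2)
  th <- atan2(yy, xx)
  s <- amp[1] * cos(kh[1] * th + pha[1]) +
       amp[2] * cos(kh[2] * th + pha[2]) +
       amp[3] * cos(kh[3] * th + pha[3])
  smax <- max(abs(range(s)), 1e-12)
  radial <- r * (1 + irregularity * s / smax)
  # a pixel belongs to the lesion if its centre is within half a pixel of
  # the deformed boundary radius
  inside <- d <= radial + 0.5
  # intensity profile: 1 at the centre tapering to 0.6 at the boundary, so
  # the mean lesion offset stays comfortably above lesion_contrast / 2
  frac <- pmin(d / pmax(radial, 1e-9), 1)
  profile <- (0.6 + 0.4 * cos(pi * frac / 2)) * inside
  list(mask = inside, profile = profile)
}

#' Generate one phantom image/mask pair
#'
#' Deterministic per seed: calling twice with an identical spec yields
#' bit-identical grids.  The mask is exactly the union of the lesion
#' supports; before noise, lesion pixels exceed the local background by at
#' least half the configured contrast on average.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `phantom_pair` with elements `image` (numeric
#'   `size x size` matrix in `[0, 1]`), `mask` (binary matrix of the same
#'   shape) and `spec`.
#' @examples
#' pair <- generate_phantom(phantom_spec(seed = 7, size = 64))
#' mean(pair$mask)
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  with_seed(spec$seed, {
    img <- phantom_background(spec$size, spec$background_texture_scale,
                              spec$dynamic_range)
    mask <- matrix(FALSE, spec$size, spec$size)
    bump <- matrix(0, spec$size, spec$size)
    if (spec$n_lesions > 0) {
      for (i in seq_len(spec$n_lesions)) {
        les <- phantom_lesion(spec$size, spec$lesion_radius_range,
                              spec$boundary_irregularity)
        mask <- mask | les$mask
        bump <- pmax(bump, les$profile)  # overlaps take the stronger profile
      }
    }
    img <- img + spec$lesion_contrast * bump
    if (spec$noise_sd > 0)
      img <- img + matrix(stats::rnorm(spec$size^2, sd = spec$noise_sd),
                          spec$size, spec$size)
    img <- pmin(pmax(img, 0), 1)
    structure(list(image = img, mask = mask * 1, spec = spec),
              class = "phantom_pair")
  })
}

#' Generate a phantom dataset with a CSV manifest
#'
#' Writes `n` image/mask PNG pairs (8-bit grayscale; masks use {0, 255}) and
#' a manifest with columns `image_path`, `mask_path`, `split`, `dataset_tag`.
#' Item `i` uses seed `base_seed + i - 1`, so datasets are reproducible and
#' extensible.
#'
#' @param n Number of pairs (>= 1).
#' @param base_seed Integer; per-item seeds are `base_seed + 0:(n-1)`.
#' @param spec_template A [phantom_spec()] whose seed is overridden per item.
#' @param dir Output directory, created if needed.  If `NULL`, nothing is
#'   written and the pairs are returned in memory.
#' @param split Split tag recorded in the manifest (e.g. "train").
#' @param dataset_tag Free-text provenance tag.
#' @return Invisibly, a list with `pairs` (when `dir` is `NULL`) or
#'   `manifest` (data frame, also written to `dir/manifest.csv`).
#' @export
generate_dataset <- function(n, base_seed, spec_template = phantom_spec(),
                             dir = NULL, split = "train",
                             dataset_tag = "phantom") {
  if (n < 1) csn_config_error("n must be >= 1")
  specs <- lapply(seq_len(n) - 1L, function(i) {
    s <- spec_template
    s$seed <- as.integer(base_seed + i)
    s
  })
  if (is.null(dir)) {
    pairs <- lapply(specs, generate_phantom)
    return(invisible(list(pairs = pairs, manifest = NULL)))
  }
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    csn_error(sprintf("cannot create output directory '%s'", dir), "csn_io_error")
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    pair <- generate_phantom(specs[[i]])
    ip <- sprintf("image_%05d.png", i)
    mp <- sprintf("mask_%05d.png", i)
    write_gray_png(pair$image, file.path(dir, ip))
    write_gray_png(pair$mask, file.path(dir, mp))
    rows[[i]] <- data.frame(image_path = ip, mask_path = mp, split = split,
                            dataset_tag = dataset_tag,
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(list(pairs = NULL, manifest = manifest))
}
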