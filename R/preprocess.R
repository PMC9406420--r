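# ROI standardization and CLAHE contrast enhancement.

#' CLAHE parameters
#'
#' @param clip_limit Positive contrast limit, expressed (as is conventional)
#'   as a multiple of the uniform histogram level; per tile, each of the 256
#'   intensity bins is capped at `clip_limit * tile_pixels / 256` and the
#'   clipped excess is redistributed over the remaining bins.  Defaults to 2,
#'   common practice in medical imaging.  `Inf` disables clipping, in which
#'   case a `(1, 1)` tile grid reduces the transform to plain global
#'   histogram equalization.
#' @param tile_grid Integer `(rows, cols)` tiling of the image, default
#'   `c(8, 8)`.
#' @export
clahe_params <- function(clip_limit = 2, tile_grid = c(8L, 8L)) {
  if (!is.numeric(clip_limit) || length(clip_limit) != 1L || clip_limit <= 0)
    csn_config_error("clip_limit must be a positive scalar")
  tile_grid <- as.integer(tile_grid)
  if (length(tile_grid) != 2L || any(tile_grid < 1L))
    csn_config_error("tile_grid must be two integers >= 1")
  structure(list(clip_limit = clip_limit, tile_grid = tile_grid),
            class = "clahe_params")
}

#' Standardize a region of interest to 256 x 256
#'
#' Crops image and mask to a half-open bounding box and resamples to
#' `out_size` x `out_size`: the image bilinearly, the mask by
#' nearest-neighbour followed by re-binarization (so the output mask is
#' strictly {0, 1}).  A full-frame bbox on an already `out_size`-sized input
#' is a no-op.
#'
#' @param image Numeric H x W matrix in `[0, 1]`.
#' @param mask Binary H x W matrix.
#' @param bbox Integer `(row0, col0, row1, col1)`, half-open (row0/col0
#'   included, row1/col1 excluded), 0-based to match typical annotation
#'   exports.  Defaults to the full frame.
#' @param out_size Output side length (default 256).
#' @param source_id,dataset_tag Provenance strings carried on the sample.
#' @return A list of class `roi_sample` with `image`, `mask`, `source_id`,
#'   `dataset_tag`.
#' @export
prepare_roi <- function(image, mask, bbox = NULL, out_size = 256L,
                        source_id = "roi", dataset_tag = "unknown") {
  if (!identical(dim(image), dim(mask)))
    csn_data_error("image and mask dimensions differ")
  H <- nrow(image); W <- ncol(image)
  if (is.null(bbox)) bbox <- c(0L, 0L, H, W)
  bbox <- as.integer(bbox)
  if (length(bbox) != 4L) csn_data_error("bbox must be (row0, col0, row1, col1)")
  r0 <- bbox[1]; c0 <- bbox[2]; r1 <- bbox[3]; c1 <- bbox[4]
  if (r0 < 0L || c0 < 0L || r1 > H || c1 > W || r1 <= r0 || c1 <= c0)
    csn_error("bbox outside image bounds or degenerate", "csn_bounds_error")
  img <- image[(r0 + 1L):r1, (c0 + 1L):c1, drop = FALSE]
  msk <- mask[(r0 + 1L):r1, (c0 + 1L):c1, drop = FALSE]
  if (!identical(dim(img), c(out_size, out_size))) {
    img <- ebi_resize(img, out_size, out_size, bilinear = TRUE)
    msk <- ebi_resize(msk, out_size, out_size, bilinear = FALSE)
  }
  msk <- (msk >= 0.5) * 1
  structure(list(image = pmin(pmax(img, 0), 1), mask = msk,
                 source_id = source_id, dataset_tag = dataset_tag),
            class = "roi_sample")
}

# clip a 256-bin tile histogram and redistribute the excess uniformly;
# a few passes push residual excess (created by the redistribution itself)
# back under the cap
clip_histogram <- function(h, cap) {
  if (!is.finite(cap)) return(h)
  for (i in 1:8) {
    excess <- sum(pmax(h - cap, 0))
    if (excess <= 1e-9) break
    h <- pmin(h, cap)
    h <- h + excess / length(h)
  }
  pmin(h, cap * (1 + 1e-9))
}

#' Contrast-limited adaptive histogram equalization
#'
#' Classic tile-based CLAHE on an intensity image in `[0, 1]`: the image is
#' quantized to 256 gray levels, a contrast-limited equalization mapping is
#' computed per tile, and each pixel is remapped by bilinear interpolation
#' between the mappings of the four surrounding tile centres (clamped at the
#' borders).  Output has the same dimensions and stays in `[0, 1]`.
#'
#' @param image Numeric matrix in `[0, 1]`, all values finite.
#' @param params A [clahe_params()].
#' @return Numeric matrix, same shape as `image`.
#' @examples
#' flat <- matrix(runif(64^2, 0.4, 0.6), 64)
#' diff(range(apply_clahe(flat)))  # wider than the 0.2 input range
#' @export
apply_clahe <- function(image, params = clahe_params()) {
  if (!all(is.finite(image))) csn_data_error("image contains non-finite pixels")
  if (min(image) < 0 || max(image) > 1)
    csn_data_error("image values must lie in [0, 1]")
  nbins <- 256L
  H <- nrow(image); W <- ncol(image)
  tr <- params$tile_grid[1]; tc <- params$tile_grid[2]
  th <- as.integer(ceiling(H / tr)); tw <- as.integer(ceiling(W / tc))
  Hp <- th * tr; Wp <- tw * tc
  # reflect-pad to a whole number of tiles
  ridx <- c(seq_len(H), rev(seq_len(H)))[seq_len(Hp)]
  cidx <- c(seq_len(W), rev(seq_len(W)))[seq_len(Wp)]
  q <- matrix(pmin(as.integer(floor(image[ridx, cidx] * nbins)), nbins - 1L),
              Hp, Wp)
  npix <- th * tw
  cap <- params$clip_limit * npix / nbins
  # per-tile equalization mappings, bins x tiles (tiles in row-major order)
  maps <- matrix(0, nbins, tr * tc)
  for (j in seq_len(tc)) {
    for (i in seq_len(tr)) {
      tile <- q[(i - 1L) * th + seq_len(th), (j - 1L) * tw + seq_len(tw)]
      h <- tabulate(as.vector(tile) + 1L, nbins)
      h <- clip_histogram(h, cap)
      maps[, (j - 1L) * tr + i] <- cumsum(h) / sum(h)
    }
  }
  # bilinear blend between the 4 neighbouring tile mappings; tile centres
  # are at (i - 1/2) * tile_size, border pixels clamp to the edge tiles
  ty <- pmin(pmax((seq_len(Hp) - 0.5) / th - 0.5, 0), tr - 1)
  tx <- pmin(pmax((seq_len(Wp) - 0.5) / tw - 0.5, 0), tc - 1)
  y0 <- pmin(floor(ty), tr - 1); fy <- ty - y0
  x0 <- pmin(floor(tx), tc - 1); fx <- tx - x0
  y1 <- pmin(y0 + 1, tr - 1); x1 <- pmin(x0 + 1, tc - 1)
  out <- matrix(0, Hp, Wp)
  qv <- q + 1L
  tile_of <- function(xi, yi) maps[, xi * tr + yi + 1L]
  # group pixels by their (x-tile cell) so each block is one vectorized lookup
  for (jcell in unique(x0)) {
    cols <- which(x0 == jcell)
    for (icell in unique(y0)) {
      rows <- which(y0 == icell)
      blockq <- qv[rows, cols, drop = FALSE]
      m00 <- matrix(tile_of(jcell, icell)[blockq], length(rows))
      m10 <- matrix(tile_of(jcell, min(icell + 1, tr - 1))[blockq], length(rows))
      m01 <- matrix(tile_of(min(jcell + 1, tc - 1), icell)[blockq], length(rows))
      m11 <- matrix(tile_of(min(jcell + 1, tc - 1),
                            min(icell + 1, tr - 1))[blockq], length(rows))
      wy <- fy[rows]; wx <- fx[cols]
      a <- m00 * (1 - wy) + m10 * wy
      b <- m01 * (1 - wy) + m11 * wy
      out[rows, cols] <- a * rep(1 - wx, each = length(rows)) +
                         b * rep(wx, each = length(rows))
    }
  }
  pmin(pmax(out[seq_len(H), seq_len(W), drop = FALSE], 0), 1)
}

#' Global histogram equalization (reference mapping)
#'
#' Direct CDF remapping of the 256-level quantized image, the limiting case
#' of [apply_clahe()] with one tile and no clipping.  Exposed mainly for
#' verification and teaching.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param nbins Quantization levels (default 256).
#' @export
global_hist_equalize <- function(image, nbins = 256L) {
  q <- pmin(as.integer(floor(image * nbins)), nbins - 1L)
  h <- tabulate(q + 1L, nbins)
  cdf <- cumsum(h) / sum(h)
  matrix(cdf[q + 1L], nrow(image), ncol(image))
}
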