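# Image and manifest I/O.
#
# Images travel as numeric H x W matrices in [0, 1]; on disk they are 8-bit
# (or 16-bit) grayscale PNG, masks 8-bit PNG with {0, 255} encoding {0, 1}.

# bilinear / nearest-neighbour resampling via EBImage; `m` is an H x W
# matrix whose first dimension maps to EBImage's first spatial dimension.
ebi_resize <- function(m, d1, d2 = d1, bilinear = TRUE) {
  img <- EBImage::Image(m)
  out <- EBImage::resize(img, w = d1, h = d2,
                         filter = if (bilinear) "bilinear" else "none")
  matrix(EBImage::imageData(out), d1, d2)
}

#' Write a grayscale image as PNG
#'
#' @param m Numeric matrix in `[0, 1]`.
#' @param path Output file.
#' @param bits Bit depth, 8 (default) or 16.
#' @export
write_gray_png <- function(m, path, bits = 8L) {
  if (!bits %in% c(8L, 16L)) csn_config_error("bits must be 8 or 16")
  m <- pmin(pmax(m, 0), 1)
  # quantize explicitly so write/read round-trips are exact
  q <- round(m * (2^bits - 1)) / (2^bits - 1)
  png::writePNG(t(q), target = path)  # writePNG expects row = y
  invisible(path)
}

#' Read a grayscale PNG (or TIFF) image
#'
#' Multichannel files are averaged to one channel.  Returns an H x W
#' numeric matrix in `[0, 1]` with the same orientation convention used by
#' [write_gray_png()].
#'
#' @param path Input file (.png, .tif or .tiff).
#' @param binarize If `TRUE`, threshold at 0.5 and return a {0, 1} mask.
#' @export
read_gray_image <- function(path, binarize = FALSE) {
  if (!file.exists(path)) csn_data_error(sprintf("image '%s' not found", path))
  ext <- tolower(tools::file_ext(path))
  a <- if (ext %in% c("tif", "tiff")) {
    EBImage::imageData(EBImage::readImage(path))
  } else {
    aperm_png(png::readPNG(path))
  }
  if (length(dim(a)) == 3L) a <- apply(a, c(1, 2), mean)
  m <- matrix(a, nrow(a), ncol(a))
  if (binarize) m <- (m >= 0.5) * 1
  m
}

# readPNG returns (y, x[, ch]); transpose back to our (H, W) = (dim1, dim2)
aperm_png <- function(a) {
  if (length(dim(a)) == 2L) t(a) else aperm(a, c(2, 1, 3))
}

#' Read a dataset manifest
#'
#' Manifests are CSV files with at least `image_path`, `mask_path`, `split`
#' and `dataset_tag` columns; paths are interpreted relative to the
#' manifest's directory.
#'
#' @param path Manifest CSV path.
#' @return Data frame with absolute `image_path` / `mask_path` columns.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path))
    csn_dependency_error(sprintf("manifest '%s' not found", path))
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_path", "mask_path")
  if (!all(need %in% names(man)))
    csn_data_error("manifest must have image_path and mask_path columns")
  base <- dirname(normalizePath(path))
  rel <- !grepl("^(/|[A-Za-z]:)", man$image_path)
  man$image_path[rel] <- file.path(base, man$image_path[rel])
  rel <- !grepl("^(/|[A-Za-z]:)", man$mask_path)
  man$mask_path[rel] <- file.path(base, man$mask_path[rel])
  man
}

# load manifest rows into in-memory samples
load_samples <- function(manifest) {
  lapply(seq_len(nrow(manifest)), function(i) {
    list(image = read_gray_image(manifest$image_path[i]),
         mask = read_gray_image(manifest$mask_path[i], binarize = TRUE),
         source_id = basename(manifest$image_path[i]),
         dataset_tag = manifest$dataset_tag[i] %||% "unknown")
  })
}
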