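#' OCT B-scan container
#'
#' A B-scan is a single grayscale cross-sectional retinal image with an
#' isotropic physical pixel scale. Rows are axial (row 0 = vitreous side,
#' depth increases with row index), columns are lateral. All row/column
#' positions reported by this package are 0-based.
#'
#' @param pixels Numeric matrix of intensities in `[0, 1]`; rows axial,
#'   columns lateral.
#' @param um_per_px Physical size of one pixel in microns (isotropic).
#'   The default, 200/33, corresponds to 33 pixels per 200 microns.
#' @param subject_id Subject identifier.
#' @param group Optional cohort label, e.g. `"case"` or `"control"`.
#' @param pair_id Optional pair identifier for matched designs.
#' @return An object of class `bscan`: a list with elements `pixels`,
#'   `um_per_px`, `subject_id`, `group`, `pair_id`.
#' @examples
#' b <- bscan(matrix(runif(64 * 64), 64, 64), subject_id = "s1")
#' dim(b$pixels)
#' @export
bscan <- function(pixels, um_per_px = 200 / 33, subject_id = "subject",
                  group = NA_character_, pair_id = NA_integer_) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop_retfreq("`pixels` must be a numeric matrix")
  if (anyNA(pixels) || any(!is.finite(pixels)))
    stop_retfreq("`pixels` must be finite")
  if (min(pixels) < 0 || max(pixels) > 1)
    stop_retfreq("intensities must lie in [0, 1]")
  if (nrow(pixels) < 64 || ncol(pixels) < 64)
    stop_retfreq("B-scan must be at least 64 x 64 pixels")
  if (!is.numeric(um_per_px) || length(um_per_px) != 1 || um_per_px <= 0)
    stop_retfreq("`um_per_px` must be a positive scalar")
  structure(
    list(pixels = pixels, um_per_px = um_per_px, subject_id = subject_id,
         group = group, pair_id = pair_id),
    class = "bscan")
}

#' Read a B-scan from an 8-bit grayscale PNG or TIFF file
#'
#' Multi-channel images are collapsed to grayscale by averaging channels.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @inheritParams bscan
#' @return A [bscan] object.
#' @export
read_bscan <- function(path, um_per_px = 200 / 33,
                       subject_id = sub("\\.[^.]+$", "", basename(path)),
                       group = NA_character_, pair_id = NA_integer_) {
  ext <- tolower(sub(".*\\.", "", path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop_retfreq("the 'tiff' package is required to read TIFF files")
    tiff::readTIFF(path)
  } else stop_retfreq("unsupported image format: .", ext)
  if (length(dim(img)) == 3) img <- apply(img, c(1, 2), mean)
  bscan(img, um_per_px = um_per_px, subject_id = subject_id,
        group = group, pair_id = pair_id)
}

#' Write a B-scan as an 8-bit grayscale PNG
#'
#' Intensities are quantized to 8 bits with round-half-even rounding.
#'
#' @param b A [bscan] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bscan <- function(b, path) {
  stopifnot(inherits(b, "bscan"))
  q <- round(b$pixels * 255) / 255
  png::writePNG(q, target = path)
  invisible(path)
}

#' @export
print.bscan <- function(x, ...) {
  cat(sprintf("<bscan> %s  %d x %d px  %.4f um/px  group=%s pair=%s\n",
              x$subject_id, nrow(x$pixels), ncol(x$pixels), x$um_per_px,
              x$group, as.character(x$pair_id)))
  invisible(x)
}
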