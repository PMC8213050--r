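#' Replace everything outside a domain with the domain mean
#'
#' @param domain A [domain_image].
#' @return List with `image` (full-size matrix: masked pixels unchanged,
#'   all others set to the mean intensity of the masked pixels),
#'   `fill_value`, and the `mask`.
#' @export
mean_fill <- function(domain) {
  stopifnot(inherits(domain, "domain_image"))
  if (!any(domain$mask)) stop_retfreq("domain mask is empty")
  fill <- mean(domain$pixels[domain$mask])
  img <- domain$pixels
  img[!domain$mask] <- fill
  list(image = img, fill_value = fill, mask = domain$mask)
}

#' Flatten an image to the ISOS junction
#'
#' Shifts each column vertically by the integer amount
#' `reference_row - round(isos[col])`, so that after flattening the rounded
#' ISOS row is constant. Integer shifts (no interpolation) are used so that
#' no spectral content is injected; vacated rows are filled with
#' `fill_value`.
#'
#' @param image Matrix to flatten (typically the [mean_fill] output).
#' @param isos 0-based ISOS row per column (fractional allowed); must be
#'   present wherever the mask has content.
#' @param reference_row Target 0-based row for the ISOS junction.
#' @param fill_value Intensity for vacated rows.
#' @param mask Optional logical mask, shifted along with the image.
#' @return List with `image`, `mask`, and `shift` (per-column integer
#'   shifts applied).
#' @export
flatten_to_isos <- function(image, isos, reference_row, fill_value,
                            mask = NULL) {
  H <- nrow(image); W <- ncol(image)
  if (length(isos) != W) stop_retfreq("`isos` length must equal image width")
  shift <- as.integer(reference_row - round(isos))
  out <- matrix(fill_value, H, W)
  mout <- if (!is.null(mask)) matrix(FALSE, H, W)
  for (cc in seq_len(W)) {
    s <- shift[cc]
    if (is.na(s)) {
      out[, cc] <- image[, cc]
      if (!is.null(mask)) mout[, cc] <- mask[, cc]
      next
    }
    if (!is.null(mask) && any(mask[, cc])) {
      mr <- range(which(mask[, cc]))
      if (mr[1] + s < 1 || mr[2] + s > H)
        stop_retfreq("flattening shifts the domain outside the frame at ",
                     "column ", cc - 1L)
    }
    src <- seq_len(H) - s
    ok <- src >= 1L & src <= H
    out[ok, cc] <- image[src[ok], cc]
    if (!is.null(mask)) mout[ok, cc] <- mask[src[ok], cc]
  }
  list(image = out, mask = mout, shift = shift)
}

#' Ramp the lateral edges of a domain to the fill level
#'
#' Over the leftmost and rightmost `ramp_width_px` columns of the domain,
#' pixels are blended `w * original + (1 - w) * fill_value` with `w` rising
#' linearly from 0 at the outermost domain column to 1 just inside the
#' ramp.
#'
#' @param image Image matrix (already mean-filled).
#' @param mask Logical domain mask (defines the domain's column extent).
#' @param fill_value The domain mean used for blending.
#' @param ramp_width_px Ramp width in columns (>= 1, at most a third of the
#'   domain width).
#' @return The ramped image matrix.
#' @export
ramp_edges <- function(image, mask, fill_value, ramp_width_px = 16L) {
  dcols <- which(colSums(mask) > 0)
  if (!length(dcols)) stop_retfreq("mask has no domain columns")
  nd <- length(dcols)
  ramp_width_px <- as.integer(ramp_width_px)
  if (ramp_width_px < 1) stop_retfreq("`ramp_width_px` must be >= 1")
  if (ramp_width_px > nd / 3)
    stop_retfreq("`ramp_width_px` exceeds a third of the domain width")
  w <- (seq_len(ramp_width_px) - 1) / ramp_width_px
  left <- dcols[seq_len(ramp_width_px)]
  right <- dcols[nd - seq_len(ramp_width_px) + 1L]
  for (i in seq_len(ramp_width_px)) {
    image[, left[i]] <- w[i] * image[, left[i]] + (1 - w[i]) * fill_value
    image[, right[i]] <- w[i] * image[, right[i]] + (1 - w[i]) * fill_value
  }
  image
}

#' Embed an image centered in a square frame
#'
#' @param image Source matrix; both dimensions must be at most `frame_px`.
#' @param fill_value Padding intensity.
#' @param frame_px Frame side length (default 800).
#' @return `frame_px` x `frame_px` matrix with the source centered at
#'   offset `floor((frame_px - dim) / 2)`.
#' @export
embed_frame <- function(image, fill_value, frame_px = 800L) {
  H <- nrow(image); W <- ncol(image)
  if (H > frame_px || W > frame_px)
    stop_retfreq("image exceeds the ", frame_px, "-px frame")
  out <- matrix(fill_value, frame_px, frame_px)
  r0 <- floor((frame_px - H) / 2)
  c0 <- floor((frame_px - W) / 2)
  out[r0 + seq_len(H), c0 + seq_len(W)] <- image
  out
}

#' Prepare a domain image for Fourier analysis
#'
#' Composite of the four preparation steps in order: mean-intensity fill
#' outside the domain, flattening to the ISOS junction, lateral edge
#' ramping, and centered embedding in a square frame. The flattening target
#' inside the source image is chosen so that after embedding the ISOS
#' junction sits at `reference_row` of the frame.
#'
#' @param domain A [domain_image].
#' @param bs The [boundary_set] supplying the ISOS rows.
#' @param frame_px Frame side (default 800).
#' @param reference_row Target 0-based frame row for the flattened ISOS
#'   junction (default 400, the frame center).
#' @param ramp_width_px Lateral ramp width (default 16).
#' @return An object of class `prepared_image`: list with `pixels`
#'   (`frame_px` square matrix), `label`, `fill_value`, `um_per_px`,
#'   `flatten_reference_row`, `frame_px`, `subject_id`.
#' @export
prepare_domain <- function(domain, bs, frame_px = 800L, reference_row = 400L,
                           ramp_width_px = 16L) {
  stopifnot(inherits(domain, "domain_image"), inherits(bs, "boundary_set"))
  mf <- mean_fill(domain)
  isos <- interpolate_gaps(bs$rows$ISOS, max_gap = ncol(domain$pixels))
  need <- colSums(domain$mask) > 0
  if (any(is.na(isos[need])))
    stop_retfreq("ISOS missing at domain columns; cannot flatten")
  row_off <- floor((frame_px - nrow(domain$pixels)) / 2)
  fl <- flatten_to_isos(mf$image, isos, reference_row - row_off,
                        mf$fill_value, mf$mask)
  rp <- ramp_edges(fl$image, fl$mask, mf$fill_value, ramp_width_px)
  em <- embed_frame(rp, mf$fill_value, frame_px)
  structure(list(pixels = em, label = domain$label,
                 fill_value = mf$fill_value, um_per_px = domain$um_per_px,
                 flatten_reference_row = as.integer(reference_row),
                 frame_px = as.integer(frame_px),
                 subject_id = domain$subject_id),
            class = "prepared_image")
}
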