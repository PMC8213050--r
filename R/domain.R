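#' Extract an anatomical domain image
#'
#' A domain is the sub-image between two of the five boundaries. The mask
#' covers rows `[round(top), round(bottom))` per column (inclusive top,
#' exclusive bottom), which makes thickness additivity across adjacent
#' domains exact. Pixels outside the mask are left untouched here; masking
#' out happens in the spectral preparation step.
#'
#' @param b A [bscan].
#' @param bs A [boundary_set] for the same image.
#' @param label One of `"FULL"`, `"ISOS_ILM"`, `"ISOS_IPLINL"`,
#'   `"ISOS_NFLGCL"`, `"RPECH_ISOS"`.
#' @param min_coverage Minimum fraction of columns with both defining
#'   boundaries present.
#' @return An object of class `domain_image`: list with `label`, `pixels`,
#'   `mask` (logical matrix), `top`, `bottom` (0-based row vectors),
#'   `um_per_px`, `subject_id`.
#' @export
extract_domain <- function(b, bs, label, min_coverage = 0.9) {
  stopifnot(inherits(b, "bscan"), inherits(bs, "boundary_set"))
  label <- match.arg(label, DOMAIN_LABELS)
  nms <- domain_boundaries(label)
  top <- bs$rows[[nms[1]]]
  bottom <- bs$rows[[nms[2]]]
  W <- ncol(b$pixels); H <- nrow(b$pixels)
  if (length(top) != W)
    stop_retfreq("boundary set width does not match the image")
  for (i in 1:2) {
    v <- bs$rows[[nms[i]]]
    if (mean(!is.na(v)) < min_coverage)
      stop_retfreq("boundary ", nms[i], " missing in more than ",
                   round(100 * (1 - min_coverage)), "% of columns")
  }
  rt <- round(top); rb <- round(bottom)
  rows <- matrix(seq_len(H) - 1L, H, W)
  mask <- sweep(rows, 2, rt, ">=") & sweep(rows, 2, rb, "<")
  mask[, is.na(rt) | is.na(rb)] <- FALSE
  structure(list(label = label, pixels = b$pixels, mask = mask,
                 top = top, bottom = bottom, um_per_px = b$um_per_px,
                 subject_id = b$subject_id),
            class = "domain_image")
}

#' Locate the foveal center column
#'
#' Returns the column in the central third of the scan where the
#' ILM-to-ISOS distance is minimal (the foveal pit); ties return the median
#' tied column. If the distance profile is flat (no pit), falls back to the
#' image center column with a warning and attribute `fallback = TRUE`.
#'
#' @param bs A [boundary_set].
#' @param min_pit_px Minimum pit prominence (px) below the central-third
#'   median distance for a minimum to count as a pit.
#' @return 0-based integer column index, with attribute `fallback`.
#' @export
locate_fovea <- function(bs, min_pit_px = 2) {
  W <- bs$width
  cols <- seq.int(floor(W / 3) + 1L, ceiling(2 * W / 3))
  d <- bs$rows$ISOS[cols] - bs$rows$ILM[cols]
  if (all(is.na(d)))
    stop_retfreq("ILM/ISOS missing throughout the central third")
  md <- stats::median(d, na.rm = TRUE)
  lo <- min(d, na.rm = TRUE)
  if (md - lo < min_pit_px) {
    warning("no foveal pit found in the central third; using center column")
    return(structure(as.integer(floor(W / 2)), fallback = TRUE))
  }
  tied <- cols[which(!is.na(d) & d <= lo + 0.25)]
  structure(as.integer(round(stats::median(tied))) - 1L, fallback = FALSE)
}

#' Thickness profile sampled at 1-degree intervals
#'
#' Thickness of a domain at 15 retinal locations, 7 degrees temporal
#' (negative) to 7 degrees nasal (positive) of the fovea, in 1-degree
#' steps. Each sample is the single-column boundary separation at the
#' column nearest the location; locations off the image (or with missing
#' boundaries) are `NA`.
#'
#' @param domain A [domain_image].
#' @param fovea_col 0-based foveal center column (see [locate_fovea]).
#' @param um_per_deg Microns per degree of visual angle. Default assumes
#'   the scan width spans 15 degrees: `width_px * um_per_px / 15`.
#' @return An object of class `thickness_profile`: list with `domain`,
#'   `locations_deg` (-7..7), `thickness_um`, `fovea_col`, `um_per_deg`,
#'   `subject_id`.
#' @export
thickness_profile <- function(domain, fovea_col, um_per_deg = NULL) {
  stopifnot(inherits(domain, "domain_image"))
  W <- ncol(domain$pixels)
  if (is.null(um_per_deg)) um_per_deg <- W * domain$um_per_px / 15
  if (um_per_deg <= 0) stop_retfreq("`um_per_deg` must be positive")
  locs <- -7:7
  cols <- as.integer(fovea_col + round(locs * um_per_deg / domain$um_per_px))
  th <- rep(NA_real_, 15L)
  ok <- cols >= 0 & cols < W
  idx <- cols[ok] + 1L
  h_px <- round(domain$bottom[idx]) - round(domain$top[idx])
  th[ok] <- h_px * domain$um_per_px
  th[!is.na(th) & th < 0] <- NA_real_
  structure(list(domain = domain$label, locations_deg = locs,
                 thickness_um = th, fovea_col = as.integer(fovea_col),
                 um_per_deg = um_per_deg, subject_id = domain$subject_id),
            class = "thickness_profile")
}

#' Thickness profiles as a long data frame
#'
#' @param profiles A list of [thickness_profile] objects.
#' @return Data frame with columns `subject_id`, `domain`, `location_deg`,
#'   `thickness_um`.
#' @export
thickness_table <- function(profiles) {
  do.call(rbind, lapply(profiles, function(p)
    data.frame(subject_id = p$subject_id, domain = p$domain,
               location_deg = p$locations_deg,
               thickness_um = p$thickness_um)))
}
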