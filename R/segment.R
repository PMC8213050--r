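#' Segmentation parameters
#'
#' Tunables for the iterative constrained boundary search.
#'
#' @param sigma_px Scale (px) of the derivative-of-Gaussian edge operator
#'   applied down each column after 3x3 median filtering. The operator is
#'   normalized so its peak response to an ideal intensity step equals the
#'   step height.
#' @param max_jump Maximum allowed per-column row change of a boundary
#'   (continuity bound of the dynamic-programming trace).
#' @param min_grad Minimum directional edge strength (in intensity-step
#'   units) for a transition to count as found; weaker columns are marked
#'   missing.
#' @param min_separation_px Minimum axial separation imposed between a new
#'   boundary's search band and the boundaries already fixed.
#' @param max_gap_px Missing-column runs up to this length are filled by
#'   linear interpolation; longer runs stay missing.
#' @param depth_penalty Small per-column penalty (fraction of step units,
#'   scaled by relative depth) biasing the ILM trace towards the shallowest
#'   strong dark-to-light transition and the RPE/CH trace towards the
#'   deepest strong light-to-dark transition.
#' @return A list of class `segmentation_params`.
#' @export
segmentation_params <- function(sigma_px = 2, max_jump = 3, min_grad = 0.05,
                                min_separation_px = 8, max_gap_px = 20,
                                depth_penalty = 0.05) {
  structure(list(sigma_px = sigma_px, max_jump = as.integer(max_jump),
                 min_grad = min_grad,
                 min_separation_px = as.integer(min_separation_px),
                 max_gap_px = as.integer(max_gap_px),
                 depth_penalty = depth_penalty),
            class = "segmentation_params")
}

# Column-wise derivative-of-Gaussian: positive where intensity increases
# with depth (dark-to-light). Normalized so an ideal unit step yields a
# peak response of 1. Rows are replicate-padded.
column_gradient <- function(pixels, sigma = 2) {
  L <- ceiling(3 * sigma)
  w <- seq_len(L) * exp(-(seq_len(L))^2 / (2 * sigma^2))
  w <- w / sum(w)
  xp <- pad_rows(pixels, L)
  H <- nrow(pixels)
  g <- matrix(0, H, ncol(pixels))
  for (j in seq_len(L)) {
    g <- g + w[j] * (xp[(L + 1 + j):(L + H + j), , drop = FALSE] -
                       xp[(L + 1 - j):(L + H - j), , drop = FALSE])
  }
  g
}

# Maximum-reward continuous path through a reward matrix: one row per
# column, |row(c) - row(c-1)| <= max_jump. Ties break to the smaller row.
dp_trace <- function(reward, max_jump) {
  H <- nrow(reward); W <- ncol(reward)
  J <- max_jump
  S <- 2L * J + 1L
  ptr <- matrix(0L, H, W)
  D <- reward[, 1]
  M <- matrix(-Inf, H, S)
  rows <- seq_len(H)
  for (cc in 2:W) {
    Dpad <- c(rep(-Inf, J), D, rep(-Inf, J))
    for (s in seq_len(S)) M[, s] <- Dpad[rows + s - 1L]
    best <- max.col(M, ties.method = "first")
    ptr[, cc] <- best - J - 1L
    D <- reward[, cc] + M[cbind(rows, best)]
  }
  path <- integer(W)
  path[W] <- which.max(D)
  for (cc in W:2) path[cc - 1] <- path[cc] + ptr[path[cc], cc]
  path
}

# Trace one boundary in the band [rmin, rmax] (1-based, per-column vectors
# allowed). grad_dir = directional gradient (already sign-flipped for
# light-to-dark). Returns fractional 0-based rows with NA where the local
# edge strength is below min_grad, plus a failure flag.
trace_boundary <- function(grad_dir, rmin, rmax, params, depth_bias = 0) {
  H <- nrow(grad_dir); W <- ncol(grad_dir)
  rmin <- pmax(rep_len(as.numeric(rmin), W), 1)
  rmax <- pmin(rep_len(as.numeric(rmax), W), H)
  # crop to the overall row window of the band (plus refinement margin)
  r1 <- max(1L, as.integer(min(rmin)) - 2L)
  r2 <- min(H, as.integer(max(rmax)) + 2L)
  sub <- grad_dir[r1:r2, , drop = FALSE]
  Hs <- nrow(sub)
  reward <- pmax(sub, 0)
  rows <- matrix(seq_len(Hs) + (r1 - 1L), Hs, W)
  inband <- sweep(rows, 2, rmin, ">=") & sweep(rows, 2, rmax, "<=")
  if (max(reward[inband], -Inf) < params$min_grad) return(NULL)
  r <- reward
  r[!inband] <- -1e6
  if (depth_bias != 0)
    r <- r + depth_bias * params$depth_penalty * (rows - 1) / H
  path <- dp_trace(r, params$max_jump) + (r1 - 1L)   # back to full-image rows
  strength <- pmax(grad_dir, 0)[cbind(path, seq_len(W))]
  # sub-pixel refinement: centroid of directional gradient around the path
  refined <- vapply(seq_len(W), function(cc) {
    p <- path[cc]
    for (it in 1:2) {    # recentre once: the response peak straddles 2 rows
      win <- max(1L, p - 2L):min(H, p + 2L)
      g <- pmax(grad_dir[win, cc], 0)
      if (sum(g) <= 0) return(p - 1)
      ctr <- sum(win * g) / sum(g)
      p <- as.integer(round(ctr))
    }
    ctr - 1
  }, numeric(1))
  refined[strength < params$min_grad] <- NA_real_
  ok <- path >= rmin & path <= rmax
  refined[!ok] <- NA_real_
  refined
}

#' Segment the five retinal boundaries of a B-scan
#'
#' Iterative constrained search for dark-to-light and light-to-dark
#' transitions: (1) ILM as the shallowest strong dark-to-light transition;
#' (2) ISOS as the strongest dark-to-light transition below the ILM;
#' (3) RPE/CH as the deepest strong light-to-dark transition below the
#' ISOS; (4) IPL/INL as the strongest light-to-dark transition between ILM
#' and ISOS; (5) NFL/GCL as the light-to-dark transition between ILM and
#' IPL/INL. Each search is restricted to the band between already-fixed
#' boundaries; continuity is enforced by a shortest-path trace with a
#' per-column jump bound; columns without a confident transition are marked
#' missing and short gaps are interpolated.
#'
#' @param b A [bscan].
#' @param params A [segmentation_params] list.
#' @return A [boundary_set] with fractional 0-based rows.
#' @examples
#' sc <- scene_spec(speckle_cv = 0, curvature_amp_px = 0, pit_depth_px = 0)
#' r <- render_bscan(sc)
#' bs <- segment_layers(r$image)
#' max(abs(bs$rows$ISOS - r$truth$rows$ISOS))
#' @export
segment_layers <- function(b, params = segmentation_params()) {
  stopifnot(inherits(b, "bscan"))
  med <- median3x3(b$pixels)
  g <- column_gradient(med, params$sigma_px)
  H <- nrow(g); W <- ncol(g)
  sep <- params$min_separation_px

  find <- function(grad_dir, rmin, rmax, name, depth_bias = 0) {
    v <- trace_boundary(grad_dir, rmin, rmax, params, depth_bias)
    if (is.null(v))
      stop_retfreq("segmentation failure: no ", name,
                   " transition above the gradient threshold")
    interpolate_gaps(v, params$max_gap_px)
  }
  fallback <- function(v, default) ifelse(is.na(v), default, v)

  ilm <- find(g, 2L, H - 6L, "ILM", depth_bias = -1)
  ilm_f <- fallback(ilm, stats::median(ilm, na.rm = TRUE))
  isos <- find(g, round(ilm_f) + sep + 1L, H - 3L, "ISOS")
  isos_f <- fallback(isos, stats::median(isos, na.rm = TRUE))
  rpe <- find(-g, round(isos_f) + 3L, H, "RPE_CH", depth_bias = +1)
  ipl <- find(-g, round(ilm_f) + sep + 1L, round(isos_f) - 3L, "IPL_INL")
  ipl_f <- fallback(ipl, stats::median(ipl, na.rm = TRUE))
  nfl <- find(-g, round(ilm_f) + 2L, round(ipl_f) - 2L, "NFL_GCL")

  rows <- list(ILM = ilm, NFL_GCL = nfl, IPL_INL = ipl, ISOS = isos,
               RPE_CH = rpe)
  # enforce strict ordering where all present (clip sub-pixel overlaps)
  m <- do.call(rbind, rows)
  for (i in 2:5) {
    low <- m[i - 1, ] + 0.5
    bad <- !is.na(m[i, ]) & !is.na(low) & m[i, ] < low
    m[i, bad] <- low[bad]
  }
  rows <- setNames(lapply(seq_len(5), function(i) m[i, ]), BOUNDARY_NAMES)
  boundary_set(rows, max_jump = params$max_jump + 1)
}
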