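#' Specify a synthetic B-scan scene
#'
#' Describes a stylized healthy macular B-scan: a stack of five reflective
#' boundaries separating six intensity bands (vitreous, NFL, GCL+IPL,
#' INL..ONL, ISOS..RPE, choroid), a Gaussian foveal pit applied to the three
#' inner boundaries, a shared low-frequency sinusoidal axial curvature,
#' multiplicative lognormal speckle, and optional bright/dark foci.
#'
#' @param width_px,height_px Image dimensions in pixels.
#' @param um_per_px Physical pixel scale in microns (isotropic; default
#'   200/33, i.e. 33 px per 200 um).
#' @param boundary_depths Mean 0-based row positions of the five boundaries
#'   (ILM, NFL/GCL, IPL/INL, ISOS, RPE/CH), strictly increasing.
#' @param layer_reflectance Mean intensities in `[0, 1]` of the six bands:
#'   vitreous plus the five bands at/below each boundary.
#' @param curvature_amp_px,curvature_period_px Amplitude and lateral period
#'   of the sinusoidal axial curvature shared by all boundaries.
#' @param pit_depth_px,pit_width_px Depth and Gaussian sigma (both px) of
#'   the foveal pit, applied to ILM, NFL/GCL and IPL/INL only.
#' @param pit_center_col 0-based column of the pit center; `NULL` = image
#'   center.
#' @param speckle_cv Coefficient of variation of the multiplicative
#'   lognormal speckle (mean 1, sd `speckle_cv`); 0 disables noise.
#' @param foci List of [focus_spec] objects.
#' @param seed Integer RNG seed; rendering is deterministic given the spec.
#' @return An object of class `scene_spec`.
#' @examples
#' sp <- scene_spec(speckle_cv = 0)
#' out <- render_bscan(sp)
#' range(out$image$pixels)
#' @export
scene_spec <- function(width_px = 768L, height_px = 496L,
                       um_per_px = 200 / 33,
                       boundary_depths = c(ILM = 195, NFL_GCL = 206,
                                           IPL_INL = 226, ISOS = 258,
                                           RPE_CH = 270),
                       layer_reflectance = c(0.02, 0.60, 0.46, 0.24,
                                             0.80, 0.28),
                       curvature_amp_px = 8, curvature_period_px = 1536,
                       pit_depth_px = 25, pit_width_px = 45,
                       pit_center_col = NULL,
                       speckle_cv = 0.1, foci = list(), seed = 1L) {
  boundary_depths <- unname(boundary_depths)
  if (length(boundary_depths) != 5 || any(diff(boundary_depths) <= 0))
    stop_retfreq("`boundary_depths` must be 5 strictly increasing rows")
  if (length(layer_reflectance) != 6 ||
      any(layer_reflectance < 0 | layer_reflectance > 1))
    stop_retfreq("`layer_reflectance` must be 6 values in [0, 1]")
  if (speckle_cv < 0) stop_retfreq("`speckle_cv` must be >= 0")
  if (is.null(pit_center_col)) pit_center_col <- floor(width_px / 2)
  spec <- structure(
    list(width_px = as.integer(width_px), height_px = as.integer(height_px),
         um_per_px = um_per_px, boundary_depths = boundary_depths,
         layer_reflectance = layer_reflectance,
         curvature_amp_px = curvature_amp_px,
         curvature_period_px = curvature_period_px,
         pit_depth_px = pit_depth_px, pit_width_px = pit_width_px,
         pit_center_col = pit_center_col, speckle_cv = speckle_cv,
         foci = foci, seed = as.integer(seed)),
    class = "scene_spec")
  tb <- truth_boundaries(spec)       # reject specs whose boundaries cross
  m <- do.call(rbind, tb)
  if (any(apply(m, 2, function(v) any(diff(v) <= 0))))
    stop_retfreq("curvature/pit make boundaries cross; adjust the spec")
  if (min(m) < 1 || max(m) > height_px - 2)
    stop_retfreq("boundaries leave the image; adjust depths or height_px")
  for (f in spec$foci) {
    if (!inherits(f, "focus_spec")) stop_retfreq("`foci` must be focus_spec")
    if (f$center_col_px < 0 || f$center_col_px >= width_px ||
        f$center_row_px < 0 || f$center_row_px >= height_px)
      stop_retfreq("focus center outside the image")
  }
  spec
}

#' Specify a single focal lesion
#'
#' A hyper-reflective focus (positive `intensity_delta`, emulating hard
#' exudates / hyper-reflective dots) or a dark cyst-like blob (negative
#' delta). Foci are hard discs at full delta with a feathered (Gaussian,
#' sigma 0.5 px) rim outside the disc, so interior pixels carry exactly
#' `intensity_delta` while the edge is free of ringing.
#'
#' @param center_col_px,center_row_px 0-based center position.
#' @param diameter_um Physical diameter in microns (> 0).
#' @param intensity_delta Added brightness; negative for dark blobs.
#' @return An object of class `focus_spec`.
#' @export
focus_spec <- function(center_col_px, center_row_px, diameter_um,
                       intensity_delta) {
  if (diameter_um <= 0) stop_retfreq("`diameter_um` must be > 0")
  structure(list(center_col_px = center_col_px, center_row_px = center_row_px,
                 diameter_um = diameter_um, intensity_delta = intensity_delta),
            class = "focus_spec")
}

# Ground-truth boundary rows (0-based, fractional) for a scene spec:
# shared sinusoidal curvature on all five boundaries, Gaussian pit added to
# the three inner boundaries.
truth_boundaries <- function(spec) {
  cols <- seq_len(spec$width_px) - 1L
  curv <- if (spec$curvature_amp_px != 0)
    spec$curvature_amp_px * sin(2 * pi * cols / spec$curvature_period_px)
  else rep(0, spec$width_px)
  pit <- if (spec$pit_depth_px != 0)
    spec$pit_depth_px *
      exp(-(cols - spec$pit_center_col)^2 / (2 * spec$pit_width_px^2))
  else rep(0, spec$width_px)
  rows <- lapply(seq_len(5), function(i) {
    b <- spec$boundary_depths[i] + curv
    if (i <= 3) b <- b + pit                 # pit thins the inner retina only
    b
  })
  names(rows) <- BOUNDARY_NAMES
  rows
}

#' Render a synthetic B-scan
#'
#' Paints the six bands using the (curved, pitted) ground-truth boundaries,
#' adds foci, then applies multiplicative lognormal speckle (mean 1,
#' sd `speckle_cv`). Deterministic given `spec$seed`.
#'
#' @param spec A [scene_spec].
#' @param subject_id,group,pair_id Metadata forwarded to the [bscan].
#' @return List with elements `image` (a [bscan]), `truth` (a
#'   [boundary_set] of the exact boundary rows used for painting) and
#'   `foci_placed` (the list of [focus_spec]s).
#' @export
render_bscan <- function(spec, subject_id = "synthetic",
                         group = NA_character_, pair_id = NA_integer_) {
  stopifnot(inherits(spec, "scene_spec"))
  H <- spec$height_px; W <- spec$width_px
  tb <- truth_boundaries(spec)
  r0 <- seq_len(H) - 1L
  # band index per pixel: 1 = vitreous, i+1 = band at/below boundary i
  cnt <- matrix(0L, H, W)
  for (i in seq_len(5))
    cnt <- cnt + outer(r0, round(tb[[i]]), ">=")
  clean <- matrix(spec$layer_reflectance[cnt + 1L], H, W)

  if (length(spec$foci)) {
    pos <- matrix(0, H, W); neg <- matrix(0, H, W)
    cgrid <- matrix(seq_len(W) - 1L, H, W, byrow = TRUE)
    rgrid <- matrix(r0, H, W)
    for (f in spec$foci) {
      rad <- f$diameter_um / (2 * spec$um_per_px)
      disc <- (rgrid - f$center_row_px)^2 + (cgrid - f$center_col_px)^2 <=
        rad^2
      if (f$intensity_delta >= 0) pos[disc] <- pos[disc] + f$intensity_delta
      else neg[disc] <- neg[disc] + f$intensity_delta
    }
    if (any(pos > 0)) clean <- clean + pmax(pos, EBImage::gblur(pos, 0.5))
    if (any(neg < 0)) clean <- clean + pmin(neg, EBImage::gblur(neg, 0.5))
  }

  img <- if (spec$speckle_cv > 0) {
    sdlog <- sqrt(log(1 + spec$speckle_cv^2))
    noise <- with_seed(spec$seed,
                       matrix(rlnorm(H * W, meanlog = -sdlog^2 / 2,
                                     sdlog = sdlog), H, W))
    clean * noise
  } else clean
  img <- pmin(pmax(img, 0), 1)

  truth <- boundary_set(tb, max_jump = Inf)
  list(image = bscan(img, um_per_px = spec$um_per_px,
                     subject_id = subject_id, group = group,
                     pair_id = pair_id),
       truth = truth, foci_placed = spec$foci)
}

#' Specify a matched case/control synthetic cohort
#'
#' Subjects are generated in matched pairs. Both members of a pair share a
#' per-pair random draw of boundary-depth and reflectance jitter, so pairing
#' is meaningful; the case member additionally receives the perturbation
#' (foci and/or boundary offsets). With `speckle_sharing = "shared"`
#' (default) the two members also share the speckle realization, so a null
#' perturbation yields identical images within a pair; use `"independent"`
#' for difference-free cohorts with independent noise (e.g. null
#' calibration of the per-frequency tests).
#'
#' @param n_pairs Number of matched pairs (>= 2).
#' @param control_scene Template [scene_spec] for control subjects.
#' @param case_perturbation List with elements `n_foci` (count per case
#'   image), `focus_diameter_um` (`c(mean, sd)` in microns),
#'   `focus_delta` (added intensity), `focus_band` (domain label between
#'   whose boundaries foci are placed, default `"RPECH_ISOS"`), and
#'   `boundary_offset_px` (named vector of per-boundary depth offsets
#'   applied to cases, e.g. `c(ISOS = 2)`).
#' @param between_subject_jitter List with `depth_sd_px` (sd of a shared
#'   axial shift of all boundaries, plus per-boundary jitter at a quarter of
#'   that sd) and `reflectance_sd` (sd of per-band reflectance jitter).
#' @param speckle_sharing `"shared"` or `"independent"` (see above).
#' @param seed Integer RNG seed for the whole cohort.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_pairs, control_scene = scene_spec(),
                        case_perturbation = list(),
                        between_subject_jitter = list(depth_sd_px = 4,
                                                      reflectance_sd = 0.02),
                        speckle_sharing = c("shared", "independent"),
                        seed = 1L) {
  if (n_pairs < 2) stop_retfreq("`n_pairs` must be >= 2")
  stopifnot(inherits(control_scene, "scene_spec"))
  pert <- utils::modifyList(
    list(n_foci = 0L, focus_diameter_um = c(mean = 17, sd = 2),
         focus_delta = 0.3, focus_band = "RPECH_ISOS",
         boundary_offset_px = numeric(0)),
    case_perturbation)
  jit <- utils::modifyList(list(depth_sd_px = 4, reflectance_sd = 0.02),
                           between_subject_jitter)
  structure(list(n_pairs = as.integer(n_pairs), control_scene = control_scene,
                 case_perturbation = pert, between_subject_jitter = jit,
                 speckle_sharing = match.arg(speckle_sharing),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Domain label -> (top boundary, bottom boundary) names.
domain_boundaries <- function(label) {
  switch(label,
         FULL = c("ILM", "RPE_CH"),
         ISOS_ILM = c("ILM", "ISOS"),
         ISOS_NFLGCL = c("NFL_GCL", "ISOS"),
         ISOS_IPLINL = c("IPL_INL", "ISOS"),
         RPECH_ISOS = c("ISOS", "RPE_CH"),
         stop_retfreq("unknown domain label: ", label))
}

#' Render a matched case/control cohort
#'
#' @param cs A [cohort_spec].
#' @return List with `cases` and `controls` (each a list of [render_bscan]
#'   outputs), `manifest` (data frame: subject_id, group, pair_id, seed) and
#'   `foci` (data frame of ground-truth foci across all images).
#' @export
render_cohort <- function(cs) {
  stopifnot(inherits(cs, "cohort_spec"))
  tmpl <- cs$control_scene
  pert <- cs$case_perturbation
  jit <- cs$between_subject_jitter
  bn <- domain_boundaries(pert$focus_band)

  draws <- with_seed(cs$seed, lapply(seq_len(cs$n_pairs), function(p) {
    shift <- rnorm(1, 0, jit$depth_sd_px)
    local <- rnorm(5, 0, jit$depth_sd_px / 4)
    refl <- rnorm(6, 0, jit$reflectance_sd)
    seeds <- sample.int(.Machine$integer.max - 1L, 2L)
    foci_par <- if (pert$n_foci > 0)
      data.frame(col = runif(pert$n_foci, 20, tmpl$width_px - 21),
                 u_row = runif(pert$n_foci),
                 diam = pmax(4, rnorm(pert$n_foci,
                                      pert$focus_diameter_um[[1]],
                                      pert$focus_diameter_um[[2]])))
    else NULL
    list(shift = shift, local = local, refl = refl, seeds = seeds,
         foci_par = foci_par)
  }))

  make_scene <- function(d, case) {
    depths <- tmpl$boundary_depths + d$shift + d$local
    if (case && length(pert$boundary_offset_px)) {
      idx <- match(names(pert$boundary_offset_px), BOUNDARY_NAMES)
      depths[idx] <- depths[idx] + unname(pert$boundary_offset_px)
    }
    refl <- pmin(pmax(tmpl$layer_reflectance + d$refl, 0), 1)
    seed <- if (cs$speckle_sharing == "shared") d$seeds[1]
    else if (case) d$seeds[1] else d$seeds[2]
    sp <- scene_spec(width_px = tmpl$width_px, height_px = tmpl$height_px,
                     um_per_px = tmpl$um_per_px, boundary_depths = depths,
                     layer_reflectance = refl,
                     curvature_amp_px = tmpl$curvature_amp_px,
                     curvature_period_px = tmpl$curvature_period_px,
                     pit_depth_px = tmpl$pit_depth_px,
                     pit_width_px = tmpl$pit_width_px,
                     pit_center_col = tmpl$pit_center_col,
                     speckle_cv = tmpl$speckle_cv, seed = seed)
    if (case && !is.null(d$foci_par)) {
      tb <- truth_boundaries(sp)
      top <- tb[[bn[1]]]; bot <- tb[[bn[2]]]
      foci <- lapply(seq_len(nrow(d$foci_par)), function(i) {
        cc <- d$foci_par$col[i]
        ci <- round(cc) + 1L
        lo <- round(top[ci]) + 2; hi <- round(bot[ci]) - 3
        rr <- lo + d$foci_par$u_row[i] * max(hi - lo, 0)
        focus_spec(cc, rr, d$foci_par$diam[i], pert$focus_delta)
      })
      sp <- scene_spec(width_px = sp$width_px, height_px = sp$height_px,
                       um_per_px = sp$um_per_px,
                       boundary_depths = sp$boundary_depths,
                       layer_reflectance = sp$layer_reflectance,
                       curvature_amp_px = sp$curvature_amp_px,
                       curvature_period_px = sp$curvature_period_px,
                       pit_depth_px = sp$pit_depth_px,
                       pit_width_px = sp$pit_width_px,
                       pit_center_col = sp$pit_center_col,
                       speckle_cv = sp$speckle_cv, foci = foci,
                       seed = sp$seed)
    }
    sp
  }

  cases <- vector("list", cs$n_pairs)
  controls <- vector("list", cs$n_pairs)
  manifest <- NULL
  foci_df <- NULL
  for (p in seq_len(cs$n_pairs)) {
    d <- draws[[p]]
    sp_case <- make_scene(d, case = TRUE)
    sp_ctrl <- make_scene(d, case = FALSE)
    id_case <- sprintf("case_%03d", p)
    id_ctrl <- sprintf("control_%03d", p)
    cases[[p]] <- render_bscan(sp_case, subject_id = id_case,
                               group = "case", pair_id = p)
    controls[[p]] <- render_bscan(sp_ctrl, subject_id = id_ctrl,
                                  group = "control", pair_id = p)
    manifest <- rbind(manifest,
                      data.frame(subject_id = c(id_case, id_ctrl),
                                 group = c("case", "control"),
                                 pair_id = p,
                                 seed = c(sp_case$seed, sp_ctrl$seed)))
    if (length(sp_case$foci))
      foci_df <- rbind(foci_df, do.call(rbind, lapply(sp_case$foci, function(f)
        data.frame(subject_id = id_case,
                   center_col_px = f$center_col_px,
                   center_row_px = f$center_row_px,
                   diameter_um = f$diameter_um,
                   intensity_delta = f$intensity_delta))))
  }
  if (is.null(foci_df))
    foci_df <- data.frame(subject_id = character(0), center_col_px = numeric(0),
                          center_row_px = numeric(0), diameter_um = numeric(0),
                          intensity_delta = numeric(0))
  list(cases = cases, controls = controls, manifest = manifest, foci = foci_df)
}

#' Write a rendered cohort to disk
#'
#' One 8-bit grayscale PNG per subject plus `manifest.csv`,
#' `boundaries.csv` (ground truth, long format) and `foci.csv`.
#'
#' @param cohort Output of [render_cohort].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- cohort$manifest
  man$image <- file.path(dir, paste0(man$subject_id, ".png"))
  all_subj <- c(cohort$cases, cohort$controls)
  bdf <- NULL
  for (s in all_subj) {
    write_bscan(s$image, file.path(dir, paste0(s$image$subject_id, ".png")))
    b <- as.data.frame(s$truth)
    b$subject_id <- s$image$subject_id
    bdf <- rbind(bdf, b)
  }
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(bdf, file.path(dir, "boundaries.csv"), row.names = FALSE)
  utils::write.csv(cohort$foci, file.path(dir, "foci.csv"), row.names = FALSE)
  invisible(dir)
}
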