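#' Radial power spectrum for one subject
#'
#' Runs the full per-subject chain: (optionally) segment the B-scan,
#' extract the requested domain, prepare it (fill, flatten, ramp, embed)
#' and compute the radial power spectrum.
#'
#' @param subject A [render_bscan] result, or a list with elements `image`
#'   (a [bscan]) and optionally `truth` (a [boundary_set]).
#' @param label Domain label (default `"RPECH_ISOS"`, the deep domain).
#' @param boundaries `"truth"` to use the generator's ground-truth
#'   boundaries (synthetic subjects only), `"auto"` to run
#'   [segment_layers].
#' @param params [segmentation_params] for `boundaries = "auto"`.
#' @param ... Passed to [prepare_domain].
#' @return A `power_spectrum`.
#' @export
subject_spectrum <- function(subject, label = "RPECH_ISOS",
                             boundaries = c("truth", "auto"),
                             params = segmentation_params(), ...) {
  boundaries <- match.arg(boundaries)
  bs <- if (boundaries == "truth") {
    if (is.null(subject$truth)) stop_retfreq("subject has no truth boundaries")
    subject$truth
  } else segment_layers(subject$image, params)
  dom <- extract_domain(subject$image, bs, label)
  compute_spectrum(prepare_domain(dom, bs, ...))
}

#' Spectra for every subject of a rendered cohort
#'
#' @param cohort Output of [render_cohort].
#' @inheritParams subject_spectrum
#' @return List with `case_spectra` and `control_spectra` (pair-aligned).
#' @export
cohort_spectra <- function(cohort, label = "RPECH_ISOS",
                           boundaries = c("truth", "auto"),
                           params = segmentation_params(), ...) {
  boundaries <- match.arg(boundaries)
  list(case_spectra = lapply(cohort$cases, subject_spectrum, label = label,
                             boundaries = boundaries, params = params, ...),
       control_spectra = lapply(cohort$controls, subject_spectrum,
                                label = label, boundaries = boundaries,
                                params = params, ...))
}

#' Thickness profiles for every subject of a rendered cohort
#'
#' @param cohort Output of [render_cohort].
#' @param label Domain label.
#' @param boundaries `"truth"` or `"auto"` (see [subject_spectrum]).
#' @param params [segmentation_params] for `boundaries = "auto"`.
#' @return List with `case_profiles` and `control_profiles`.
#' @export
cohort_thickness <- function(cohort, label = "RPECH_ISOS",
                             boundaries = c("truth", "auto"),
                             params = segmentation_params()) {
  boundaries <- match.arg(boundaries)
  one <- function(subject) {
    bs <- if (boundaries == "truth") subject$truth
    else segment_layers(subject$image, params)
    dom <- extract_domain(subject$image, bs, label)
    fov <- suppressWarnings(locate_fovea(bs))
    thickness_profile(dom, fov)
  }
  list(case_profiles = lapply(cohort$cases, one),
       control_profiles = lapply(cohort$controls, one))
}
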