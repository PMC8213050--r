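#' Paired t-test on a vector of differences
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` with `df = n - 1`. One-tailed p is
#' reported in the stated direction. A zero-variance difference vector is
#' degenerate: p is 0 if the mean lies strictly in the hypothesized
#' direction, else 1.
#'
#' @param d Numeric vector of paired differences (length >= 2, finite).
#' @param direction `"greater"` tests mean(d) > 0, `"less"` mean(d) < 0.
#' @return List with `t`, `df`, `p_one_tailed`, `p_two_tailed`,
#'   `degenerate`.
#' @examples
#' paired_t(c(1, 2, 3))  # t = 3.4641, one-tailed p = 0.0371
#' @export
paired_t <- function(d, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (length(d) < 2) stop_retfreq("need at least 2 pairs")
  if (anyNA(d) || any(!is.finite(d))) stop_retfreq("differences must be finite")
  n <- length(d)
  m <- mean(d)
  s <- sd(d)
  if (s == 0) {
    in_dir <- if (direction == "greater") m > 0 else m < 0
    return(list(t = if (m == 0) 0 else sign(m) * Inf, df = n - 1,
                p_one_tailed = if (in_dir) 0 else 1,
                p_two_tailed = if (m == 0) 1 else 0,
                degenerate = TRUE))
  }
  t <- m / (s / sqrt(n))
  df <- n - 1
  p1 <- if (direction == "greater") pt(t, df, lower.tail = FALSE)
  else pt(t, df)
  list(t = t, df = df, p_one_tailed = p1,
       p_two_tailed = 2 * pt(-abs(t), df), degenerate = FALSE)
}

# Reorder control entries to match case pair ids; error on broken pairing.
match_pairs <- function(case_ids, control_ids) {
  idx <- match(case_ids, control_ids)
  if (anyNA(idx) || anyDuplicated(case_ids))
    stop_retfreq("broken pairing; unpaired: ",
                 paste(unique(c(case_ids[is.na(idx)],
                                setdiff(control_ids, case_ids))),
                       collapse = ", "))
  if (length(setdiff(control_ids, case_ids)))
    stop_retfreq("broken pairing; unpaired: ",
                 paste(setdiff(control_ids, case_ids), collapse = ", "))
  idx
}

#' Per-frequency paired one-tailed tests between matched cohorts
#'
#' At every frequency bin, the paired case-minus-control power differences
#' are tested with a one-tailed paired t-test in a hypothesized direction
#' that depends on the spatial period: cases (the diabetic-like group) are
#' hypothesized to have more power at high spatial frequencies (periods at
#' or below `direction_split_um`), controls more power at low frequencies.
#' Maximal runs of consecutive significant bins (same direction) of length
#' at least `min_band_len` are reported as bands on the microns-per-cycle
#' axis; shorter significant runs are listed separately as singletons.
#'
#' @param case_spectra,control_spectra Lists of `power_spectrum` objects.
#' @param case_pair_ids,control_pair_ids Pair identifiers aligning the two
#'   lists (defaults: positional pairing).
#' @param direction_split_um Period (microns/cycle) at or below which the
#'   hypothesized direction is case > control; above it, control > case.
#' @param alpha Per-bin significance level.
#' @param min_band_len Minimum run length for a band (default 2).
#' @return An object of class `cohort_comparison`: list with `tests` (data
#'   frame per bin: `bin_k`, `period_um`, `mean_case`, `mean_control`, `t`,
#'   `df`, `p`, `direction`, `significant`), `bands`, `singletons`,
#'   `alpha`, `n_pairs`, `direction_split_um`.
#' @export
per_frequency_tests <- function(case_spectra, control_spectra,
                                case_pair_ids = NULL,
                                control_pair_ids = NULL,
                                direction_split_um = 22, alpha = 0.05,
                                min_band_len = 2L) {
  if (length(case_spectra) != length(control_spectra))
    stop_retfreq("case and control lists differ in length")
  if (length(case_spectra) < 3) stop_retfreq("need >= 3 pairs")
  if (!is.null(case_pair_ids)) {
    idx <- match_pairs(case_pair_ids, control_pair_ids)
    control_spectra <- control_spectra[idx]
  }
  kmax <- length(case_spectra[[1]]$power)
  ok <- vapply(c(case_spectra, control_spectra),
               function(s) length(s$power) == kmax, TRUE)
  if (!all(ok)) stop_retfreq("mismatched frequency axes")
  cm <- do.call(rbind, lapply(case_spectra, function(s) s$power))
  gm <- do.call(rbind, lapply(control_spectra, function(s) s$power))
  period <- case_spectra[[1]]$period_um
  n <- nrow(cm)
  d <- cm - gm
  dirs <- ifelse(period <= direction_split_um, "case_gt_control",
                 "control_gt_case")
  res <- lapply(seq_len(kmax), function(k) {
    tt <- paired_t(d[, k],
                   direction = if (dirs[k] == "case_gt_control") "greater"
                   else "less")
    c(t = tt$t, df = tt$df, p = tt$p_one_tailed)
  })
  res <- do.call(rbind, res)
  tests <- data.frame(bin_k = seq_len(kmax), period_um = period,
                      mean_case = colMeans(cm), mean_control = colMeans(gm),
                      t = res[, "t"], df = res[, "df"], p = res[, "p"],
                      direction = dirs,
                      significant = res[, "p"] < alpha)
  runs <- rle(paste0(tests$significant, ".", tests$direction))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  band_rows <- function(keep) {
    out <- NULL
    for (i in which(keep)) {
      ks <- starts[i]:ends[i]
      out <- rbind(out, data.frame(
        k_lo = min(ks), k_hi = max(ks),
        period_um_hi = period[min(ks)], period_um_lo = period[max(ks)],
        p_min = min(tests$p[ks]), p_max = max(tests$p[ks]),
        direction = tests$direction[min(ks)], n_bins = length(ks)))
    }
    if (is.null(out))
      out <- data.frame(k_lo = integer(0), k_hi = integer(0),
                        period_um_hi = numeric(0), period_um_lo = numeric(0),
                        p_min = numeric(0), p_max = numeric(0),
                        direction = character(0), n_bins = integer(0))
    out
  }
  sig <- startsWith(runs$values, "TRUE")
  structure(list(tests = tests,
                 bands = band_rows(sig & runs$lengths >= min_band_len),
                 singletons = band_rows(sig & runs$lengths < min_band_len),
                 alpha = alpha, n_pairs = n,
                 direction_split_um = direction_split_um),
            class = "cohort_comparison")
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat(sprintf("<cohort_comparison> %d pairs, %d bins, alpha = %g\n",
              x$n_pairs, nrow(x$tests), x$alpha))
  if (nrow(x$bands)) {
    cat("significant bands:\n")
    print(x$bands, row.names = FALSE)
  } else cat("no significant bands\n")
  invisible(x)
}

#' Paired two-tailed thickness comparison between matched cohorts
#'
#' Per sampled location: group means and SDs, and a paired two-tailed
#' t-test of the case-minus-control differences. Pairs missing a value at a
#' location are dropped at that location (pairwise deletion).
#'
#' @param case_profiles,control_profiles Lists of [thickness_profile]
#'   objects for the same domain, aligned by pair (or via pair ids).
#' @param case_pair_ids,control_pair_ids Optional pair identifiers.
#' @return Data frame with columns `domain`, `location_deg`, `mean_case`,
#'   `sd_case`, `mean_control`, `sd_control`, `n_pairs`, `t`, `p`.
#' @export
thickness_tests <- function(case_profiles, control_profiles,
                            case_pair_ids = NULL, control_pair_ids = NULL) {
  if (length(case_profiles) != length(control_profiles))
    stop_retfreq("case and control lists differ in length")
  if (!is.null(case_pair_ids)) {
    idx <- match_pairs(case_pair_ids, control_pair_ids)
    control_profiles <- control_profiles[idx]
  }
  dom <- unique(c(vapply(case_profiles, function(p) p$domain, ""),
                  vapply(control_profiles, function(p) p$domain, "")))
  if (length(dom) != 1) stop_retfreq("profiles mix domains")
  cm <- do.call(rbind, lapply(case_profiles, function(p) p$thickness_um))
  gm <- do.call(rbind, lapply(control_profiles, function(p) p$thickness_um))
  locs <- case_profiles[[1]]$locations_deg
  out <- lapply(seq_along(locs), function(j) {
    keep <- !is.na(cm[, j]) & !is.na(gm[, j])
    d <- cm[keep, j] - gm[keep, j]
    if (length(d) < 2)
      return(data.frame(domain = dom, location_deg = locs[j],
                        mean_case = mean(cm[, j], na.rm = TRUE),
                        sd_case = sd(cm[, j], na.rm = TRUE),
                        mean_control = mean(gm[, j], na.rm = TRUE),
                        sd_control = sd(gm[, j], na.rm = TRUE),
                        n_pairs = length(d), t = NA_real_, p = NA_real_))
    tt <- paired_t(d)
    data.frame(domain = dom, location_deg = locs[j],
               mean_case = mean(cm[keep, j]), sd_case = sd(cm[keep, j]),
               mean_control = mean(gm[keep, j]),
               sd_control = sd(gm[keep, j]),
               n_pairs = length(d), t = tt$t, p = tt$p_two_tailed)
  })
  do.call(rbind, out)
}

#' Ordinary least-squares regression of thickness on age
#'
#' @param thickness Numeric response (e.g. regional thickness in microns).
#' @param age Numeric predictor (years); must vary.
#' @return List with `slope`, `intercept`, `r_squared`, `n`.
#' @examples
#' age_regression(c(300, 290, 286), c(50, 60, 70))  # slope -0.7
#' @export
age_regression <- function(thickness, age) {
  keep <- !is.na(thickness) & !is.na(age)
  thickness <- thickness[keep]; age <- age[keep]
  if (length(age) < 3) stop_retfreq("need >= 3 subjects")
  if (sd(age) == 0) stop_retfreq("age has zero variance")
  fit <- lm(thickness ~ age)
  tss <- sum((thickness - mean(thickness))^2)
  r2 <- if (tss == 0) 0 else 1 - sum(residuals(fit)^2) / tss
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = r2, n = length(age))
}

#' @importFrom stats coef residuals setNames median
NULL
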