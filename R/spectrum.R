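# Cache of radial bin-index maps, keyed by frame size.
.radial_cache <- new.env(parent = emptyenv())

radial_bins <- function(frame_px) {
  key <- as.character(frame_px)
  if (!is.null(.radial_cache[[key]])) return(.radial_cache[[key]])
  half <- frame_px / 2
  u <- seq.int(-half, half - 1)
  r <- sqrt(outer(u^2, u^2, "+"))
  k <- as.integer(floor(r + 0.5))      # annuli [k - 0.5, k + 0.5)
  .radial_cache[[key]] <- k
  k
}

#' 2D Fourier power spectrum of a prepared image
#'
#' Power is `|F|^2` of the unnormalized forward DFT, returned
#' origin-centered (zero frequency at index `frame/2 + 1` in both
#' dimensions). Conjugate symmetry of real input and Parseval's identity
#' (`sum(|F|^2) / N^2 == sum(pixel^2)`) hold exactly up to float error.
#'
#' @param prep A [prepared_image], or a square numeric matrix.
#' @return Origin-centered power matrix.
#' @export
fft_power_2d <- function(prep) {
  x <- if (inherits(prep, "prepared_image")) prep$pixels else prep
  if (!is.matrix(x) || nrow(x) != ncol(x))
    stop_retfreq("input must be a square matrix")
  if (anyNA(x) || any(!is.finite(x)))
    stop_retfreq("non-finite pixels in FFT input")
  P <- Mod(stats::fft(x))^2
  n <- nrow(P)
  idx <- c((n / 2 + 1):n, 1:(n / 2))   # fftshift for even n
  P[idx, idx]
}

#' Reduce a 2D power spectrum to a 1D radial spectrum
#'
#' Bin `k` collects the sum of power over all frequency samples whose
#' radial frequency (cycles/frame) lies in `[k - 0.5, k + 0.5)`; the DC
#' term is stored separately. The bins partition the plane exactly, so
#' `dc_power + sum(power)` equals the total 2D power. The physical period
#' axis is `period_um[k] = frame_px * um_per_px / k`; at the native scale
#' of 33 px per 200 microns and an 800-px frame the fundamental bin
#' (k = 1) has a period of 4848.48 microns/cycle. Bins beyond
#' `frame_px / 2` collect the corner frequencies above the axial/lateral
#' Nyquist.
#'
#' @param power2d Origin-centered power matrix (from [fft_power_2d]).
#' @param um_per_px Physical pixel scale in microns.
#' @param subject_id,label Metadata carried into the spectrum.
#' @return An object of class `power_spectrum`: list with `k` (1..kmax),
#'   `power`, `period_um`, `dc_power`, `log_power` (log10), `um_per_px`,
#'   `frame_px`, `subject_id`, `label`.
#' @export
radial_reduce <- function(power2d, um_per_px = 200 / 33,
                          subject_id = NA_character_, label = NA_character_) {
  n <- nrow(power2d)
  kmap <- radial_bins(n)
  sums <- rowsum(as.vector(power2d), as.vector(kmap))
  kv <- as.integer(rownames(sums))
  kmax <- max(kv)
  power <- numeric(kmax)
  power[kv[kv >= 1L]] <- sums[kv >= 1L, 1]
  dc <- if (any(kv == 0L)) sums[kv == 0L, 1] else 0
  k <- seq_len(kmax)
  structure(list(k = k, power = power,
                 period_um = n * um_per_px / k,
                 dc_power = dc,
                 log_power = suppressWarnings(log10(power)),
                 um_per_px = um_per_px, frame_px = n,
                 subject_id = subject_id, label = label),
            class = "power_spectrum")
}

#' Compute the radial power spectrum of a prepared domain image
#'
#' Convenience composite of [fft_power_2d] and [radial_reduce].
#'
#' @param prep A [prepared_image].
#' @return A `power_spectrum` (see [radial_reduce]).
#' @export
compute_spectrum <- function(prep) {
  stopifnot(inherits(prep, "prepared_image"))
  radial_reduce(fft_power_2d(prep), um_per_px = prep$um_per_px,
                subject_id = prep$subject_id, label = prep$label)
}

#' Spectrum list as a long data frame
#'
#' @param spectra List of `power_spectrum` objects.
#' @return Data frame with columns `subject_id`, `domain`, `bin_k`,
#'   `period_um`, `power`, `log10_power`.
#' @export
spectrum_table <- function(spectra) {
  do.call(rbind, lapply(spectra, function(s)
    data.frame(subject_id = s$subject_id, domain = s$label, bin_k = s$k,
               period_um = s$period_um, power = s$power,
               log10_power = s$log_power)))
}

#' Per-subject z-scores of spectral power
#'
#' At each frequency bin, power is standardized by the mean and sample
#' standard deviation (n - 1) over a reference set of subjects:
#' `z = (power - mu_k) / sigma_k`. Bins where the reference SD is zero are
#' marked missing.
#'
#' @param spectra List of `power_spectrum` objects sharing domain and axis.
#' @param reference Character vector of subject ids forming the reference
#'   set (default: all subjects); at least 3.
#' @return An object of class `zscore_table`: list with `z` (subjects x
#'   bins matrix, rownames = subject ids), `mu`, `sigma`, `period_um`,
#'   `reference`.
#' @export
power_zscores <- function(spectra, reference = NULL) {
  ids <- vapply(spectra, function(s) s$subject_id, "")
  if (anyDuplicated(ids)) stop_retfreq("duplicate subject ids")
  doms <- unique(vapply(spectra, function(s) s$label, ""))
  if (length(doms) != 1) stop_retfreq("spectra mix domains: ",
                                      paste(doms, collapse = ", "))
  ks <- vapply(spectra, function(s) length(s$power), 1L)
  if (length(unique(ks)) != 1) stop_retfreq("mismatched frequency axes")
  if (is.null(reference)) reference <- ids
  if (!all(reference %in% ids)) stop_retfreq("reference ids not in spectra")
  if (length(reference) < 3) stop_retfreq("need >= 3 reference subjects")
  mat <- do.call(rbind, lapply(spectra, function(s) s$power))
  rownames(mat) <- ids
  ref <- mat[reference, , drop = FALSE]
  mu <- colMeans(ref)
  sigma <- apply(ref, 2, sd)
  z <- sweep(sweep(mat, 2, mu, "-"), 2, sigma, "/")
  z[, sigma == 0] <- NA_real_
  structure(list(z = z, mu = mu, sigma = sigma,
                 period_um = spectra[[1]]$period_um, reference = reference),
            class = "zscore_table")
}
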