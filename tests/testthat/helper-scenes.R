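# Shared fixtures, all generated in code.

# Small, flat, noise-free scene with the canonical example boundary rows.
flat_scene <- function(depths = c(40, 60, 90, 140, 165), height = 220,
                       width = 256, speckle = 0, foci = list(), seed = 1) {
  scene_spec(width_px = width, height_px = height,
             boundary_depths = depths, curvature_amp_px = 0,
             pit_depth_px = 0, speckle_cv = speckle, foci = foci,
             seed = seed)
}

# Default-anatomy scene (pit + curvature) at full width.
study_scene <- function(..., seed = 1) scene_spec(..., seed = seed)

# A hand-built domain_image (bypasses segmentation) for prep unit tests.
manual_domain <- function(pixels, top, bottom, label = "FULL",
                          um_per_px = 200 / 33) {
  H <- nrow(pixels); W <- ncol(pixels)
  top <- rep_len(top, W); bottom <- rep_len(bottom, W)
  rows <- matrix(seq_len(H) - 1L, H, W)
  mask <- sweep(rows, 2, round(top), ">=") & sweep(rows, 2, round(bottom), "<")
  structure(list(label = label, pixels = pixels, mask = mask, top = top,
                 bottom = bottom, um_per_px = um_per_px,
                 subject_id = "manual"),
            class = "domain_image")
}

# A synthetic power_spectrum object with given power values.
manual_spectrum <- function(power, subject_id, um_per_px = 200 / 33,
                            frame_px = 800, label = "RPECH_ISOS") {
  k <- seq_along(power)
  structure(list(k = k, power = power,
                 period_um = frame_px * um_per_px / k, dc_power = 0,
                 log_power = suppressWarnings(log10(power)),
                 um_per_px = um_per_px, frame_px = frame_px,
                 subject_id = subject_id, label = label),
            class = "power_spectrum")
}

mae <- function(a, b) mean(abs(a - b), na.rm = TRUE)
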