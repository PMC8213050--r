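---
title: "Spatial-frequency analysis of retinal B-scans: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial-frequency analysis of retinal B-scans: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retfreq)
```

## The problem

Retinal thickening is the standard quantitative criterion for managing
diabetic eye disease, but early diabetic change — hyper-reflective foci,
hard-exudate precursors, small-vessel remodeling — can alter the *texture*
of the retina in optical coherence tomography (OCT) cross-sections before
any thickness change is measurable. `retfreq` quantifies that texture as a
spatial-frequency power spectrum of anatomically delimited sub-images
("domains") of a B-scan, and compares matched case/control cohorts
frequency by frequency. Features tens of microns across (the size scale of
hyper-reflective foci) live at mid-range spatial frequencies, roughly
15–30 µm/cycle at typical OCT sampling.

## Coordinate and intensity conventions

Images are matrices with rows axial (row 0 at the vitreous side, depth
increasing downward) and columns lateral. All reported row/column positions
are 0-based. Intensities are floats in [0, 1] in memory and 8-bit grayscale
PNG (round-half-even) on disk. The physical scale is isotropic,
33 px per 200 µm (≈ 6.0606 µm/px) by default.

## The synthetic B-scan generator

No patient images ship with the package, so validation rests on a
generator with exact ground truth. A scene is:

* five boundary surfaces (ILM, NFL/GCL, IPL/INL, ISOS, RPE/CH) separating
  six constant-reflectance bands (vitreous 0.02, NFL 0.60, GCL+IPL 0.46,
  INL–ONL 0.24, ISOS–RPE 0.80, choroid 0.28). The default depths
  (195, 206, 226, 258, 270 of a 496-row, 768-column frame) give a deep
  RPE/CH-to-ISOS domain of 12 px ≈ 73 µm, matching typical clinical
  values, while keeping every inter-boundary gap wide enough (≥ 11 px)
  that each transition is resolvable by a σ = 2 px edge operator;
* a single low-frequency sinusoidal axial curvature (default amplitude
  8 px, period 1536 px) shared by all boundaries — this is what the
  flattening step exists to remove;
* a Gaussian foveal pit (depth 25 px, σ 45 px) applied to the three inner
  boundaries only, so the inner retina thins toward the fovea while the
  outer bands stay put;
* multiplicative lognormal speckle with mean 1 and a configurable
  coefficient of variation (default 0.1) — strictly positive, the standard
  proxy for coherent-imaging noise;
* optional foci: hard discs of configurable physical diameter carrying an
  intensity offset, with an outward-feathered Gaussian rim (σ = 0.5 px).
  The rim is feathered *outward* (`pmax` of the disc and its blur) rather
  than blurring the disc itself, so that pixels inside the disc carry
  exactly the nominal delta — a plain blur of a ~3 px disc would dilute
  its interior by ~15 %, making "inject a +0.3 focus" mean something else.

Cohorts are generated in matched pairs: both members share a per-pair draw
of boundary-depth jitter (a shared axial shift with SD 4 px plus
per-boundary jitter at a quarter of that) and reflectance jitter
(SD 0.02), and, by default, the speckle realization
(`speckle_sharing = "shared"`), so a pair differs only by the case
perturbation. Shared speckle makes the paired design maximally sensitive
and makes a null perturbation produce literally identical pairs — useful
for bookkeeping tests. For null-calibration studies the
`"independent"` mode draws separate speckle for the two members, which is
what a difference-free comparison of distinct eyes actually looks like.

What the generator does *not* emulate: wave-optics speckle correlation,
depth-dependent signal roll-off, vessel shadows, motion artifacts, or the
intensity statistics of any particular instrument. Passing tests
demonstrate that the pipeline recovers known structure under this model,
not that it reproduces any clinical measurement.

## Layer segmentation

Boundaries are found as dark-to-light or light-to-dark transitions of the
column-wise intensity profile, in the classic iterative, constrained
order, each search restricted to the band between boundaries already
fixed:

1. ILM — shallowest strong dark-to-light transition;
2. ISOS — strongest dark-to-light transition below the ILM;
3. RPE/CH — deepest strong light-to-dark transition below the ISOS;
4. IPL/INL — strongest light-to-dark transition between ILM and ISOS;
5. NFL/GCL — light-to-dark transition between ILM and IPL/INL.

(The IPL/INL is located before the NFL/GCL because it is the stronger of
the two inner light-to-dark transitions; the NFL/GCL search is then
constrained above it.)

The edge operator is a derivative-of-Gaussian (σ = 2 px) down each column
of a 3×3-median-filtered image, normalized so that its peak response to an
ideal step equals the step height — which makes the `min_grad` threshold
(default 0.05) interpretable as a minimum contrast. Each boundary is
traced by dynamic programming maximizing total edge strength under a
per-column jump bound (`max_jump`, default 3 px), which is both the
continuity prior and the tie-break (ties resolve to the shallower row). A
small depth penalty (0.05 step-units across the full image height) biases
the ILM to the shallowest strong edge and the RPE/CH to the deepest,
without overriding genuine contrast differences. The traced row is refined
to sub-pixel precision by the centroid of the directional gradient in a
±2 px window, re-centered once. Columns whose edge strength falls below
`min_grad` are marked missing; runs of up to 20 missing columns are closed
by linear interpolation, longer runs stay missing.

Degenerate inputs: an image with no directional gradient above threshold
anywhere in a search band raises a segmentation failure naming the first
boundary that could not be found. Manual review is replaced by
`apply_corrections()`, which substitutes user-supplied spans, re-validates
the strict inner-to-outer ordering (reporting the first offending column),
and flags the boundary as corrected.

## Domains and thickness

The five domains are FULL (ILM→RPE/CH), ISOS–ILM, ISOS–IPL/INL,
ISOS–NFL/GCL and RPE/CH–ISOS. A domain's mask covers rows
`[round(top), round(bottom))` — inclusive above, exclusive below — so
FULL = (ISOS–ILM) ⊎ (RPE/CH–ISOS) exactly, pixel for pixel, and thickness
is additive by construction.

Thickness is sampled at 15 locations, 7° temporal to 7° nasal of the
fovea in 1° steps, as the single-column boundary separation at the nearest
column times the pixel scale. The degree-to-micron conversion defaults to
`width_px × um_per_px / 15` (≈ 310 µm/deg for a 768-px scan spanning 15°),
overridable where calibration is known. A point sample (rather than a
local average) is the simplest reading of per-degree sampling; averaging
over a window is a trivial extension but changes no conclusion at the
synthetic noise levels.

The fovea is located as the column of minimal ILM-to-ISOS separation in
the central third of the scan (ties: median tied column). If the profile
has no pit (prominence < 2 px), the image center is returned with a
warning and a `fallback` attribute — flat validation scenes hit this path
deliberately.

## Spectral preparation

Each domain is prepared for the FFT in four steps, in this order:

1. **mean fill** — everything outside the mask is set to the mean
   intensity of the masked pixels, so the domain's surroundings contribute
   no structure;
2. **flatten** — every column is shifted vertically by the integer
   `reference_row − round(ISOS(col))`, removing retinal shape
   (curvature) that would otherwise masquerade as low-frequency lateral
   content. Integer shifts are deliberate: sub-pixel interpolation would
   inject spectral content into the very quantity under study. The cost is
   a ±0.5 px rounding ripple on the other boundaries; measured on a
   noise-free curved scene, the total power remaining at the curvature's
   lateral frequency after flattening is ~2 % of its unflattened value;
3. **ramp** — the outermost 16 columns (~2 % of the width) on each side of
   the domain are blended linearly to the fill level (weight 0 at the
   edge), suppressing the lateral edge discontinuity that would otherwise
   leak across all frequencies. A linear ramp is the simplest choice; the
   width is configurable;
4. **embed** — the result is centered in an 800×800 frame (offset
   `floor((800 − dim)/2)`), padded with the fill value. The flattening
   reference row is chosen so the ISOS junction lands at frame row 400,
   maximizing axial headroom.

## Power spectra and the frequency axis

Power is `|F|²` of the unnormalized 2-D DFT, origin-centered. The 2-D
spectrum is reduced to 1-D by summing annuli `[k − 0.5, k + 0.5)` in
radial frequency (cycles/frame), k = 1…; the annuli partition the plane,
so DC + Σ bins equals total power exactly, and Parseval
(`Σ|F|²/N² = Σ pixel²`) is asserted to 1e-9 in the tests. A radial (rather
than lateral-axis) reduction is used because the features of interest —
foci — are isotropic, and the radial sum uses every spectral sample.

The physical axis is `period_um[k] = 800 × um_per_px / k`; at
33 px / 200 µm that is 4848.48 µm/cycle for the fundamental (k = 1) bin,
halving with each integer multiple. The frame width in microns is
conventionally quoted as the "DC" period; since a literal zero frequency
has no finite period, the true DC term is stored separately
(`dc_power`) and the fundamental carries the frame-width period. Bins
beyond k = 400 collect corner frequencies above the axial/lateral
Nyquist; they are retained for the partition identity and tested like any
other bin.

`log10(power)` is carried for display only; all statistics run on
untransformed power (a monotone transform would not preserve paired mean
differences).

Per-subject z-scores standardize power at each bin by the mean and
sample SD (n − 1) of a stated reference set; bins with zero reference SD
are marked missing.

## Cohort comparison

Per frequency bin, case-minus-control differences are tested with a
paired one-tailed t-test (`t = mean(d)/(sd(d)/√n)`, df = n − 1). The
hypothesized direction encodes the scientific expectation: cases (the
diabetic-like group) have *more* power at high spatial frequencies —
periods at or below 22 µm/cycle, the split sitting between the two
empirically reported ranges (15.5–18.2 vs 25.9–29.0 µm/cycle) — and
*less* power at longer periods, where regular lamination dominates. The
split is configurable. Zero-variance differences are degenerate: p = 0
if the mean lies strictly in the hypothesized direction, else 1.

Significant bins are reported as maximal runs of ≥ 2 consecutive
significant bins of the same direction, as period ranges with their
min/max p; singleton significant bins are listed separately. No
multiple-testing correction is applied by default (raw per-bin p-values
are the reporting convention this mirrors); Benjamini–Hochberg can be
applied to the per-bin column by the user.

Thickness is compared per domain × location with paired two-tailed
t-tests under pairwise deletion (a pair missing at a location is dropped
at that location only). `age_regression()` is a plain OLS
slope/intercept/r² utility.

### Calibration and power, and what "chance level" means here

Two properties anchor the statistics, both computed by the test suite and
the acceptance script:

* **Null calibration.** On difference-free cohorts with independent
  speckle, the per-bin one-tailed rejection rate at α = 0.05 is 0.047
  over 2400 bin-replicates (8 cohorts × 400 bins at 6 pairs each in the
  test suite) — the t-test is honest at the bin level, because each
  radial bin sums hundreds of periodogram ordinates and the paired
  differences are effectively normal.

* **Effect recovery.** Twenty-pair cohorts whose cases carry thirty
  ~17 µm bright foci in the deep domain produce a case>control
  significant band overlapping 15–19 µm/cycle in ≥ 80 % of seeds
  (11/12 at the acceptance script's default sizes; 20 seeds in the test
  suite).

  The permutation control needs care. *Neighboring radial bins are
  correlated* (a subject's spectral envelope is smooth in k), so
  two-bin chance bands appear somewhere in a ~70-bin window far more
  often than α even though every individual bin is calibrated — measured
  per-bin rejection under within-pair label permutation is 0.058. The
  α-calibrated null statistic is therefore a band *spanning* the whole
  15–19 µm window, which label permutation produces in 0 of 20 measured
  seeds, while mere two-bin overlap occurs in ~35 % of permuted seeds.
  Reports of band evidence should quote the band's span and its p-range,
  not the bare existence of a run.

## Problem sizes and numerical choices

The validation suite uses 768×496 scenes (the native width of the
instrument convention it follows), 800×800 frames, 20-pair cohorts ×
20 seeds for power, 8 × 6-pair cohorts for null calibration, and 100
random frames for the FFT identities; the acceptance script scales the
seed counts to 12/6 while keeping per-cohort sizes. Tolerances: FFT
identities 1e-9 relative; segmentation 2 px MAE under speckle CV 0.1 and
10 px curvature; thickness additivity exact in pixels (micron values agree
to float associativity); paired-t against closed-form and `t.test` oracles
to 1e-9.

## Known limitations

* The generator's piecewise-constant bands lack real intra-layer texture;
  absolute power levels are not comparable to clinical scans, only the
  machinery that measures them is validated.
* Integer-shift flattening leaves a ±0.5 px staircase on non-reference
  boundaries (~2 % residual curvature power).
* Segmentation assumes the canonical contrast ordering of a healthy-ish
  retina (IPL/INL edge stronger than NFL/GCL, ISOS band bright); severely
  disrupted anatomy should be handled through `apply_corrections()`.
* One B-scan per subject; no volume scans, no ETDRS-grid regional
  thickness.
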