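# retfreq

Spatial-frequency analysis of retinal OCT B-scans.

Retinal thickening is the workhorse criterion for managing diabetic eye
disease, but early diabetic change — hyper-reflective foci, hard-exudate
precursors, small-vessel remodeling — shows up as *texture* in
cross-sectional OCT images before thickness moves. `retfreq` is for
imaging scientists who want to quantify that texture: it segments the
five canonical retinal boundaries (ILM, NFL/GCL, IPL/INL, ISOS, RPE/CH),
cuts the B-scan into the five anatomical domains between them, and
measures each domain's 2-D Fourier power spectrum on a physically
calibrated microns-per-cycle axis, then compares matched case/control
cohorts frequency by frequency.

## The method

For a domain image *g* (everything outside the domain set to the domain's
mean intensity, flattened to the ISOS junction by integer column shifts,
lateral edges ramped to the mean, centered in an 800×800 frame):

* power spectrum: `P(u, v) = |F[g](u, v)|²` (unnormalized DFT,
  origin-centered);
* radial reduction: bin *k* sums `P` over `k − ½ ≤ √(u² + v²) < k + ½`
  cycles/frame, with DC kept separately, so the bins partition the plane
  and `DC + Σₖ Pₖ = Σ P` exactly;
* physical axis: `period_um[k] = 800 · um_per_px / k`; at the native
  33 px / 200 µm scale the fundamental bin sits at 4848.48 µm/cycle;
* per bin, matched pairs are compared with a paired one-tailed t-test
  `t = mean(d) / (sd(d)/√n)`, df = n − 1, with the hypothesized direction
  case > control for periods ≤ 22 µm/cycle (fine texture) and
  control > case above (regular lamination); runs of ≥ 2 consecutive
  significant bins are reported as bands, and per-subject z-scores
  `z = (P − μₖ)/σₖ` are computed against a reference group.

Thickness profiles (15 samples, 7° temporal to 7° nasal, paired
two-tailed t-tests) and OLS age regressions are included.

No patient images are distributed; a synthetic B-scan generator
(layer stack, foveal pit, axial curvature, multiplicative lognormal
speckle, injectable bright foci and dark blobs, matched-pair cohorts with
shared jitter) provides exact ground truth for validation and power
studies.

## Worked example

Render a 20-pair cohort whose cases carry thirty ~17 µm bright foci in
the deep domain (RPE/CH to ISOS), and compare the cohorts:

```r
library(retfreq)

cs  <- cohort_spec(20, case_perturbation = list(n_foci = 30), seed = 42)
coh <- render_cohort(cs)
sp  <- cohort_spectra(coh, label = "RPECH_ISOS", boundaries = "truth")
per_frequency_tests(sp$case_spectra, sp$control_spectra)
#> <cohort_comparison> 20 pairs, 566 bins, alpha = 0.05
#> significant bands:
#>  k_lo k_hi period_um_hi period_um_lo        p_min      p_max       direction n_bins
#>   221  265     21.93885     18.29617 1.222643e-09 0.03171453 case_gt_control     45
#>   267  270     18.15912     17.95735 9.363783e-03 0.02223846 case_gt_control      4
#>   274  277     17.69520     17.50356 1.092482e-02 0.04549499 case_gt_control      4
#>   296  301     16.38002     16.10792 5.462798e-03 0.02866558 case_gt_control      6
```

The cases carry significantly more power in bands between ~16 and
~22 µm/cycle — the physical size scale of the injected foci — while, as
expected for a texture-only perturbation, their thickness is unchanged:

```r
th <- cohort_thickness(coh, label = "RPECH_ISOS", boundaries = "truth")
head(thickness_tests(th$case_profiles, th$control_profiles)[,
     c("location_deg", "mean_case", "mean_control", "p")], 4)
#>   location_deg mean_case mean_control p
#> 1           -7    72.121       72.121 1
#> 2           -6    71.818       71.818 1
#> 3           -5    72.727       72.727 1
#> 4           -4    72.424       72.424 1
```

For real images, replace the generator with `read_bscan()` +
`segment_layers()` (and `apply_corrections()` where review is needed),
then the same `extract_domain()` → `prepare_domain()` →
`compute_spectrum()` chain.

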