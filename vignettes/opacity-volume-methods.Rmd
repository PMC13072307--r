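---
title: "Opacity volume measurement: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Opacity volume measurement: models, parameters, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octovm)
```

## The measurement problem

Corneal scarring shows up in spectral-domain OCT as hyperreflective stromal
tissue. Because scar severity varies strongly between eyes even after
identical injuries, cross-sectional group comparisons are noisy; the robust
design is longitudinal, following the *same* cornea over weeks and using each
eye as its own control. That requires a measurement that is stable across
sessions: a fixed, calibrated pair of intensity thresholds applied to
geometrically standardized volumes.

`octovm` implements that pipeline. A volume (depth `z` x A-scans `x` x
B-scans `y`) passes through:

1. **Registration** (`register_bscans`): each B-scan is shifted axially by an
   integer maximizing the normalized cross-correlation of its mean A-line
   profile against the previous, already-registered B-scan. This removes
   heartbeat/respiration jitter. The first B-scan anchors the chain.
2. **Button crop** (`crop_button`): voxels outside a cylinder (default radius
   1 mm, auto-centred on the brightest-surface centroid) are cleared, so
   eyelids and peripheral tissue never reach the thresholds.
3. **Specular clearing** (`remove_specular`): the saturated vertical stripe at
   the apex is removed by zeroing a constant-size column band in every B-scan,
   auto-detected as the largest contiguous group of columns that saturate
   (>= the 99.5th volume percentile) in at least 80% of B-scans.
4. **Surface detection** (`detect_surface`): the volume is binarized at the
   button threshold, residual artifacts are removed by keeping the largest
   connected component, and per-A-scan first/last crossings give the anterior
   and posterior surfaces, despiked with a 5x5 median filter.
5. **Flattening** (`flatten_volume`): every A-scan is shifted so the anterior
   surface lies on one reference row. Integer shifts only -- interpolation
   would redistribute intensities and silently move the thresholds.
6. **Anterior trim** (`trim_anterior_fraction`): everything deeper than
   `ref_row + fraction x median thickness` is cleared. The default fraction
   of 2/3 keeps the anterior stroma, where the wound lives, removes iris/lens
   clutter (posterior to the trim plane once the cornea is flat), and avoids
   the depth-dependent signal falloff that would destabilize fixed thresholds.
7. **Dual-threshold segmentation** (`segment_button`, `segment_opacity`,
   `measure_opacity`): voxels `>= t_button` form the corneal button; voxels
   `> t_opacity` within the button are hyperreflective opacity. Percent
   opacity is `100 x |opacity| / |button|` on voxel counts, so spacing
   metadata cannot bias the ratio.

## Threshold calibration

`calibrate_thresholds` fixes both cutoffs from scar-free cohorts processed
through the same geometric stages:

* `t_button` is the mean intensity of all nonzero voxels in the
  button-calibration cohort (normal corneas segmented from background).
* `t_opacity` is an upper percentile of corneal-voxel intensities pooled over
  the naive cohort; signal above the naive ceiling is what "hyperreflective"
  means. A `mean + k x SD` variant is available behind the `method` switch.

**Why the default percentile is 99.5.** An empirical percentile threshold has
a false-positive floor of exactly `100 - p` percent of the corneal field, by
construction: that fraction of *normal* stroma exceeds the cutoff whatever
the noise model. At `p = 99` the floor is ~1 percentage point, which alone is
a +19% relative error on a 5% opacity -- the smallest burden the eligibility
rule admits. At `p = 99.5` the floor is ~0.5 points, keeping the
false-positive contribution inside the assay's recovery envelope while still
detecting essentially all scar voxels lying well above the naive ceiling.
`opacity_percentile = 99` remains one argument away and is exercised in the
test suite.

Ties at `t_opacity` count as normal tissue (strict `>`), the conservative
scar call; the button uses `>=`.

## The synthetic phantom world

No public volumes accompany the assay, so validation runs on phantoms
(`phantom_spec`, `generate_phantom`) whose truth is known analytically
*before* noise: a spherical-cap anterior surface (default radius 7 mm) over a
hyporeflective background (level 20), a stromal shell of constant
surface-referenced thickness (110 um at 2 um/voxel = 55 voxels), an
ellipsoidal scar of known voxel volume, exponential axial falloff
(0.002/voxel), multiplicative lognormal speckle (sdlog 0.10), a saturated
specular stripe, posterior iris/lens clutter, and a smoothed-random-walk
axial jitter per B-scan (max 6 voxels) that mimics quasi-periodic
heartbeat/respiration rather than white noise.

Parameter choices worth recording:

* **Grid**: the default 256 x 200 x 40 grid over a 4 x 4 mm field is the
  desk-scale stand-in for the acquisition's 1024 x 1000 x 100 geometry, which
  remains available as a configuration.
* **Axial spacing 2 um/voxel**: not stated by the source instrument's print;
  consistent with commercial SD-OCT, and it puts a ~100 um rodent cornea at
  >= 50 voxels of thickness, enough for the anterior-fraction arithmetic.
* **Curvature radius 7 mm**: with voxels 10x finer axially than laterally, a
  rodent-like 1.4 mm radius would push the peripheral cap outside the
  desk-scale axial range, leaving too few A-scans with a rendered shell. The
  human-like 7 mm default keeps ~70% of A-scans on the shell while preserving
  the multi-curve geometry that makes isolation hard; it is configurable.
* **Speckle sdlog 0.10**: emulates the residual contrast of averaged SD-OCT
  B-scans (raw speckle is far stronger, but clinical exports are
  frame-averaged). It creates genuine tail overlap between normal and
  scarred intensity distributions -- the problem the dual threshold exists to
  solve -- without burying the shell edge.
* **Scar model**: the ellipsoid lives in the *surface-referenced* frame (its
  axial coordinate is depth below the local anterior surface), so it follows
  the stromal lamellae like a real anterior scar, its voxel count equals
  `4/3 pi abc`, and a laterally wide scar can exist inside a curved shell --
  impossible for a straight ellipsoid in scanner coordinates.
  `scar_for_fraction` sizes semi-axes to a target percentage of the anterior
  analysis field, laterally isotropic in millimetres.
* **Clutter moves with the eye**: bulk heartbeat/respiration motion shifts
  cornea and iris/lens together, so clutter is rendered before the jitter
  shift. Only the specular stripe, a scanner-frame artifact, is overlaid
  after. This also anchors profile cross-correlation: with a stationary
  clutter slab, registration would lock onto the artifact instead of the
  anatomy.

What a green phantom test does **not** establish: physical realism of OCT
interferometry (no polarization, no vendor noise spectra), lateral motion
(the generator jitters axially only, and the pipeline corrects axially only),
refraction of the optical path, or the behaviour of the thresholds under
instrument drift between sessions. The phantom validates the *computational*
contract -- geometry handling, threshold semantics, volumetric bookkeeping --
not the instrument.

## Numerical choices and degenerate inputs

* **Connectivity bridging.** Clearing the specular band zeroes a full column
  slab through every B-scan, which necessarily splits the binarized cornea
  into two 6-connected components. `detect_surface` and `segment_button`
  therefore evaluate connectivity on an x-dilated copy of the binary mask
  (radius `bridge_px`, default 8) and map the largest component back onto the
  undilated mask. The mask itself is never dilated.
* **Despiking, not smoothing.** The 5x5 surface median filter replaces a
  value only when it deviates from its window median by more than 2 voxels.
  A plain median filter biases a terraced, anisotropically sampled curved
  surface by +-1 voxel in the interior and by much more at one-sided boundary
  windows; despiking removes genuine outliers (residual reflections) while
  leaving accurate detections untouched, which is what makes post-flatten
  surfaces land exactly on the reference row.
* **Integer axial shifts everywhere** (registration, flattening): intensity
  histograms are preserved exactly, so thresholds calibrated once remain
  meaningful after geometry correction.
* **Registration reference** is the previous registered B-scan, matching
  sequential physiological drift; a flat (zero-variance) profile gets shift 0
  with a warning rather than an undefined correlation.
* **Surface failure** is explicit: if fewer than half of the A-scans carrying
  any signal yield a surface crossing, detection errors out rather than
  flattening garbage.
* **Thickness fallback**: when no posterior surface exists, the trim stage
  requires an explicit fixed-depth fallback and warns that it used it.
* **Percentile 100** makes `t_opacity` the sample maximum; an equal-intensity
  scar is then undetectable. Documented edge, tested.

## Reliability and statistics

`icc_two_way_random_absolute` estimates the single- and average-measures
intraclass correlations under the two-way random-effects, absolute-agreement
model, with F-based 95% confidence intervals (McGraw & Wong construction;
the average-measures interval applies the k-measure aggregation to the
single-measures bounds). The implementation is validated against an
independent reference implementation (pingouin) on a frozen fixture, against
the population variance ratio on simulated tables, and against the exact
algebraic identity `ICC_avg = k r / (1 + (k-1) r)` to 10 significant digits.
Interpretation cutpoints: < 0.5 poor, 0.5-0.75 fair, 0.75-0.9 good, > 0.9
excellent (0.9 itself is "good").

The group statistics are the nonparametric suite appropriate for small
per-group counts: tie-corrected Kruskal-Wallis with Dunn post hoc
z-statistics (Bonferroni-adjusted -- the companion default of the usual
graphing software; the source names Dunn without an adjustment), Mann-Whitney
U with exact enumeration for groups of <= 8 and a tie-corrected normal
approximation otherwise (deterministic switch), the coefficient of variation
as 100 x SD/mean, per-interval percent weekly change, a strict > 5
percentage-point eligibility filter relative to the pre-injury baseline, and
the printed sample-size formula `n = ceil(1 + 2 C (s/d)^2)` (the ceiling
because fractional animals are not a valid n). For that formula with the
stated constants (C = 10.51, s = 20, d = 30) the arithmetic gives 11 per
group; the source text asserts 6 -- the operation implements the printed
formula and leaves the discrepancy visible rather than resolving it.

Session spacing of the repeat ratings (reported inconsistently as 24 h and
48 h in the source material) is treated as metadata only; no computation
depends on it.

## Design choices where the design was open

* **Bit depth**: exported volumes are 8-bit by default, 16-bit supported;
  the source does not state the export depth.
* **Button radius**: standardized but unstated; default 1.0 mm, and the
  validation experiments use 2.2 mm so the entire phantom cornea (including
  truth voxels) lies inside the cylinder and measured percentages are
  comparable to mask-based truth.
* **Button-threshold averaging**: "mean intensity of the samples" is read as
  the mean over nonzero voxels of the preprocessed volumes (background zeros
  carry no information about tissue); flagged because the alternative
  (corneal voxels only) is equally defensible.
* **Config format**: JSON (the only structured-config parser guaranteed in
  the runtime environment).
* **Validation comparisons** are made against the truth restricted to the
  same analysis field the pipeline measures (button cylinder intersected with
  the anterior fraction): percent opacity is a ratio over the analyzed field
  by definition, so truth and measurement must share the denominator.

## Known limitations

* **ICC interval coverage with two raters.** The F-based absolute-agreement
  interval under-covers when the rater variance is non-negligible and
  `k = 2`: the rater component then has a single degree of freedom, its
  variance estimate is median-biased toward zero, and the interval sits
  high. Simulation (n = 30 subjects, component SDs 3/1/1) puts the true
  coverage of the nominal 95% interval near 87% rather than 95%, with the
  misses below the lower bound; the corresponding acceptance check is left
  failing by design rather than papered over. The point estimates and the
  interval construction match the independent reference implementation
  exactly, so this is a property of the standard interval, not of this
  implementation.

* No lateral (x/y) registration; axial-only motion is assumed, as in the
  phantom.
* The TIFF layer reads/writes uncompressed single-channel grayscale
  multi-page files only (8/16-bit), the format the pipeline itself produces
  and FIJI exports; compressed or RGB TIFFs are rejected with a clear error.
* The reliability layer assumes complete tables; missing cells are an error,
  not an imputation problem.
* CoV requires a positive mean; it is not defined for signed quantities like
  weekly changes and the package refuses to compute it there.
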