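---
title: "Spatiotemporal cluster mapping of plantar pressure: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatiotemporal cluster mapping of plantar pressure: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedocluster)
```

## The analysis problem

Pedobarometric footplates record the distribution of the vertical ground
reaction force under the sole as a movie of pressure frames on a regular
sensor grid (here 5 mm pitch, 25 mm^2 cells, 5 kPa resolution, 10 kPa
detection threshold, 100 Hz). Comparing such recordings between two groups
of walkers — for example, female and male adults walking barefoot at a
self-selected pace — raises two methodological problems that this package
addresses end to end:

1. **Anatomical alignment.** Feet differ in size, position and orientation
   on the plate. Before any pixel-wise comparison, each footprint must be
   mapped onto a common coordinate system.
2. **Mass-univariate inference.** Testing thousands of pixels (or dozens of
   time points) inflates the family-wise error rate (FWER). The package
   uses cluster-based permutation inference with a max-statistic null,
   which controls the FWER exactly under group exchangeability without
   parametric assumptions about the spatial correlation of pressure.

The pipeline: stance segmentation → landmark-based standardization →
parameter extraction (gait, pressure, M-shape temporal structure, time
series including the centre of pressure) → scalar group statistics →
spatial and temporal cluster-based permutation tests.

## Foot standardization

Two landmarks define the foot axis: the most posterior point of the heel
(Landmark 1) and the tip of the second toe (Landmark 2). Standardization
rotates the pressure data about Landmark 1 until the L1–L2 axis is
parallel to the walking-progression axis, scales uniformly so that the
landmark distance is 100 arbitrary units (A.U.), and resamples pressures
onto a fixed grid by bilinear interpolation (values outside the source
support are 0). The transform is a proper similarity, so landmark-anchored
distance ratios are preserved exactly; the enforced postcondition is a
transformed landmark distance of 100 ± 1e-6 A.U.

Decisions where the method was genuinely open:

* **Grid resolution.** The standard grid spans 120 A.U. along the
  progression axis and 60 A.U. mediolaterally; the default resolution is
  one cell per A.U. (120 × 60). Coarser grids (e.g. 40 × 20 for
  simulation studies) cover the same extent with larger cells. Nothing in
  the method depends on the resolution beyond interpolation smoothness.
* **What is interpolated.** Pressures (kPa), not per-sensor forces, are
  interpolated; total force is conserved under regridding to well within
  2% because the integral of a bilinear interpolant matches the source on
  smooth fields.
* **Left feet** are mirrored about the progression axis by default so that
  medial/lateral structures align with right-foot anatomy; per-side
  analyses are still run separately, mirroring only makes region masks and
  templates side-agnostic.
* **Foot angle sign.** The raw angle is `atan2(dcol, drow)`; the sign is
  flipped for left feet so external rotation is positive bilaterally.

Weight normalization divides pressures by body weight (mass × g with
g = 9.8 m/s^2); total force is alternatively expressed as a percentage of
body weight (BW%).

## The M-shaped force curve and its temporal parameters

During stance, total vertical force typically rises to a load-response
maximum (Peak 1), dips to a mid-stance minimum (Peak 2, the "valley") and
rises again to a push-off maximum (Peak 3). Contact time is split at the
three peaks into Intervals 1–4 (ms) and Proportional Intervals 1–4 (% of
contact time, summing to 100 by construction). Transient Phases 1 and 2
are the frame midpoints of (Peak 1, Peak 2) and (Peak 2, Peak 3), with
half-frame ties rounded toward the earlier frame for determinism.

Peak detection locates local maxima on a lightly smoothed copy of the
series (moving average, window 3), requires the two dominant maxima to be
at least 10% of the series length apart, and takes the valley as the raw
minimum between them. Each extremum is then refined by fitting a parabola
on a ±3-frame window and rounding the vertex to the nearest frame; this
averages out frame-level noise without changing clean inputs. The
refinement is rejected when the quadratic lack-of-fit is of the same order
as the fitted curvature (as for piecewise-linear extrema, which have no
meaningful sub-frame vertex) or when the vertex strays more than 1.5
frames. Series without a triphasic structure (monotone, single-peaked, or
valley not below both peaks) are flagged invalid and excluded from
peak-anchored analyses only; their contact-area and COP series remain in
the temporal analyses.

Time series (total force in BW%, averaged pressure over activated sensors,
contact area, COP x/y) are resampled to 50 points (100 in the
high-resolution robustness variant) by a natural cubic spline over
normalized time [0, 1]; spline overshoot below zero of the non-negative
series is clamped. Frames inside a stance with no activated sensor have an
undefined COP; these are filled by linear interpolation from neighbouring
frames and counted in an attribute.

## Cluster-based permutation inference

For each pixel of the standardized weight-normalized maps (or each time
point of a series), a two-sample t statistic is computed — Welch by
default, because the motivating use case compares groups of very different
size (68 vs 24) where pooled variance is not defensible; a pooled-variance
option exists. A pixel enters testing only if it is non-zero in at least
50% of the subjects of *each* group (`min_group_coverage`); this avoids
degenerate variances at footprint margins where only a few subjects make
contact. Points super-threshold at the cluster-forming level (two-sided
p < .01) are split by sign and joined into clusters under 8-connectivity
(index adjacency in 1D). The cluster-level statistic is the **cluster
mass**, the sum of |t| over members — chosen over the largest |t| in the
cluster for its sensitivity to spatially extended effects; the max-|t|
variant is available behind `perm_config(cluster_stat = "max_t")`.

The null distribution of the *maximum* cluster statistic over both signs
is built from label permutations that preserve group sizes (default 1000
Monte Carlo draws; the testable mask is fixed at its observed-label value).
Corrected p-values use the positively biased estimator
`(1 + #(null >= observed)) / (1 + n_perm)`, which cannot fall below
`1/(n_perm + 1)`; when the number of distinct relabelings does not exceed
`n_perm` the implementation enumerates all of them and reports exact
proportions instead. A cluster is significant when its corrected p-value
is at or below `cluster_alpha` (default .05). Because the permutation
distribution is exact under exchangeability, the FWER is controlled at
`cluster_alpha` regardless of the noise distribution — the package asserts
this by simulation (500 null cohorts of 12 vs 12 subjects on a 40 × 20
grid with 200 permutations each, a problem size chosen so the whole
simulation runs in about a minute; the empirical rate must fall in
[0.03, 0.08]).

Covariate-adjusted *cluster* inference is deliberately out of scope (no
accepted method exists); covariate adjustment is provided for scalar
parameters only, via ordinary least squares on sex (male = 0, female = 1),
age, BMI, cadence, foot angle and walking speed, with variance inflation
factors from `car::vif`.

## The synthetic cohort generator

No public raw data accompany the motivating study, so the package ships a
generator whose defaults encode that study's population: 68 female and 24
male walkers; per-sex anthropometrics (age 34.5 ± 14.9 / 33.7 ± 14.4 y,
height 159.4 ± 4.8 / 172.8 ± 4.9 cm, weight 54.9 ± 7.3 / 70.1 ± 9.1 kg,
BMI derived); step duration 0.490 ± 0.030 / 0.524 ± 0.048 s, step length
0.702 ± 0.060 / 0.724 ± 0.063 m, foot angle 3.04 ± 4.37 / 6.35 ± 3.73°;
proportional intervals (26.4, 24.0, 24.8, 24.9) ± (3.1, 2.9, 3.6, 2.7) %
for females and (24.3, 20.7, 28.9, 26.1) ± (3.1, 4.4, 6.9, 2.2) % for
males (printed means are renormalized to sum to exactly 100); contact
times equal to the per-sex interval sums (671 / 720 ms); peak total force
derived from the per-sex maximum force over body weight (≈121 / 123 BW%).
All draws are truncated normal (±3 SD), and the whole cohort is a pure
function of `(config, seed)` via per-participant substream seeds.

Quantities the study does not report were fixed once at field-realistic
values and not revisited: mid-stance valley force 75 ± 6 BW%, onset/offset
force 5 BW% (so the first and last frames register contact above the
10 kPa threshold), step width 90 mm, landmark distance 0.15 × height,
multiplicative log-normal sensor noise of SD 0.12 per sensor per frame,
and a subject-level amplitude SD of 0.08.

Model choices:

* **Footprint.** A mixture of smooth 2D Gaussian lobes (heel, lateral
  midfoot, five metatarsal heads, toes) on the standard grid, warped to
  sensor coordinates per subject by the inverse of the standardization
  transform. This produces realistic contiguous contact areas, not
  anatomical fidelity; in particular all subjects share one template, so
  between-subject shape variability of real feet is *not* emulated, and
  the synthetic contact area (≈180 cm^2) is larger than typical adult
  values. Passing tests therefore demonstrate correctness of the
  machinery, not robustness to real anatomical heterogeneity.
* **Waveform.** The total-force curve is built from half-cosine arcs
  through (onset, Peak 1, valley, Peak 3, offset). This keeps the curve
  C^1 with extrema exactly at the configured knots *and* non-degenerate
  curvature there, so that peak localization under sensor noise is a
  well-posed sub-frame estimation problem. (A monotone Hermite spline was
  rejected: its zero-derivative knots give flat peaks whose argmax wanders
  several frames under noise.)
* **Load transfer.** Zone weights shift smoothly from heel to forefoot
  across the stance (logistic transition centred at the valley, plus a
  small midfoot bump), so the COP progresses forward as in real gait and
  total force decomposes exactly into the configured waveform.
* **Device emulation.** Pressures are quantized to the 5 kPa resolution
  and thresholded at 10 kPa. The threshold removes the low-pressure skirt
  of the footprint, so the emitted peak force runs ≈4–5% below the
  configured waveform amplitude — the same truncation a real capacitive
  plate applies.
* **Regional effects.** Group effects are injected as weight-normalized
  pressure offsets on elliptical presets (calcaneus; second metatarsal) —
  uniformly within the region, the way a regional loading difference
  behaves physically. For calibrated simulation studies,
  `generate_pressure_maps()` can size a uniform offset so that the
  pointwise Cohen's d at the region's peak-template pixel equals a target
  (d is then larger at low-pressure margin pixels); the `"pixelwise"`
  alternative yields an exact d at every pixel. The per-pixel SD used for
  calibration is the analytic
  `template * sqrt((1 + sd_subj^2) * exp(sd_sensor^2) - 1)`.

## Numerical and degenerate-input conventions

* Bilinear interpolation for regridding (`pracma::interp2`), 0 outside the
  source support; negative interpolated values clamped to 0.
* Natural cubic splines (`stats::splinefun(method = "natural")`) for time
  normalization.
* Transient-phase midpoints round half down; permutation p-values use the
  `(b + 1)/(m + 1)` estimator; cluster tables are sorted by decreasing
  mass with ties left in first-occurrence order.
* All-zero recordings segment to an empty stance list; zero-variance
  testable pixels get t = 0 with a counted warning; frames with no active
  sensor get an interpolated, flagged COP.
* Connected components use a two-pass run-based union-find (8- or
  4-connectivity), validated against a naive flood fill.
* Monte Carlo permutation draws are sampled with replacement; designs with
  fewer distinct relabelings than requested permutations are warned about,
  and `method = "auto"` switches to exhaustive enumeration whenever that
  is no more work than the requested Monte Carlo draw.

## Problem sizes used by the test-suite simulations

Simulation-backed checks use deliberately scaled problem sizes chosen to
give informative Monte Carlo precision at interactive runtimes: FWER on
500 null cohorts (12 vs 12, 40 × 20 grid, 200 permutations); effect
recovery on 50 runs of 30 vs 15 subjects at a reference pointwise d of
1.2; temporal-structure recovery on 50 full-pipeline cohorts at the
default 68 vs 24 group sizes; exhaustive-oracle equivalence on a 5 vs 3
design over 8 time points (56 relabelings).

## Known limitations

* One shared footprint template: no inter-subject anatomical shape
  variation, no foot deformities, and mirrored-left anatomy is assumed
  symmetric.
* Landmarks are inputs; automatic landmark detection (and any nonrigid,
  anatomy-aware registration) is out of scope.
* Covariate adjustment exists only for scalar parameters, not for
  cluster-level inference.
* The coverage rule (50% per group) is a pragmatic mask; pixels with
  systematically one-sided contact (e.g. toe margins) are excluded from
  inference rather than modelled.
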