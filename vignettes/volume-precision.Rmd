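---
title: "Measuring the precision of CT volumetry: models, simulator and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the precision of CT volumetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(volprec)
```

## The measurement model

A hand-traced volumetric measurement on CT proceeds slice by slice: an
observer outlines the organ's cross-section on each image where it appears,
the workstation reports each region-of-interest area `A_j` (cm²), and the
volume is estimated by slice summation,

$$V = \sum_j A_j \, t_j / 10 \quad [\mathrm{cm}^3],$$

with `t_j` the nominal slice thickness in mm. `volprec` implements exactly
this estimator (`volume_from_stack()`), deliberately without end-cap or
partial-volume corrections: the point of the package is to characterize the
precision of the method clinicians actually use, and the estimator's
behaviour at coarse slice thickness is part of that method. Contour areas
use the shoelace formula, treating the traced polygon as ideal (zero line
width) and implicitly closed; an explicitly repeated closing vertex is
deduplicated on input because freehand ROI tools export both conventions.

Units are fixed package-wide — mm for lengths, cm² for areas, cm³ for
volumes — and coordinates have no fixed origin, since areas depend only on
relative vertex positions.

Repeatedly measuring a *stable* organ then turns measurement noise into an
observable: the series coefficient of variation `COV = SD/mean`
(`series_summary()`) is the relative precision of the whole chain —
scanner, slice alignment, observer, software. Sample SD (`n−1`) is used
throughout; series are short (5–20 scans) and the unbiased estimator is the
convention in repeatability work.

## Minimal detectable change

Given a test–retest series (n measurements, mean m, SD s), the inferential
question is: how large must a true volume change be before a two-sided
paired t-test at level α can see it? `min_detectable_volume_change()`
models the post-change assessment as a second, independent measurement
series with the same SD, so paired differences have SD `√2·s` and `n−1`
degrees of freedom:

$$\delta = t_{1-\alpha/2,\,n-1}\,\sqrt{2}\,s\,/\,(\sqrt{n}\,m).$$

This is the only reading of "paired t-test on n repeated measurements" that
reproduces the textbook α-ratio between the 1% and 5% thresholds
(`t_{0.995}/t_{0.975} = 1.367` at n = 20); for the canonical adrenal
example (m = 3.4 cm³, s = 0.64 cm³, n = 20) it yields 12.46% at α = 0.05
and 17.03% at α = 0.01. Reported values for this exercise in the
radiology literature (13.0% / 17.8%) are slightly larger; the arithmetic
behind them is not documented, so `volprec` treats them as upper bounds and
does not attempt to match them exactly. The alternative "shift-only" model
(differences SD = s, no √2) is available via `model = "shift-only"`.

`significance_of_observed_change()` inverts the same statistic to a
p-value, and `classify_change()` applies the pragmatic screening rule: an
observed fractional change within the documented precision COV for objects
of that size (≈0.18 for adrenal-sized organs at 5 mm slices) is "within
precision"; only larger changes are candidates for true change. Equality is
classified as within precision — at the boundary one should *not* call a
response.

Isotropic-growth conversions link the volumetric and unidimensional
(RECIST) worlds: `ΔL = (1+ΔV)^{1/3} − 1` and its inverse
(`volume_change_to_linear()`, `linear_change_to_volume()`), plus the pixel
geometry helpers `pixel_size()` (FOV/matrix) and
`pixel_error_linear_fraction()` showing why single-pixel cursor errors
already swamp the linear equivalent of a detectable volume change for
centimeter-scale lesions. `expected_aging_drift()` converts an absolute
growth rate (default 0.03 cm³/yr, the reported adrenal aging drift) into a
fractional change, to check that slow physiologic drift is negligible
against measurement noise.

## The phantom simulator

`phantom_spec()` + `simulate_longitudinal_series()` emulate the whole
measurement study on a lesion of known geometry: sphere, ellipsoid, or a
bilobed union of two ellipsoids (an adrenal-like shape; its cross-section
union area is computed by 0.1 mm grid rasterization, accurate to well under
0.5% at the sizes simulated, and its boundary by ray casting from the
midpoint, which requires the union to remain star-shaped — keep the lobes
overlapping).

Each simulated scan applies, in order:

1. **Slice alignment** — the slice grid is offset by `u ~ Uniform(0, t)`;
   areas are sampled at slice-center planes (the simplest model of the
   area-times-thickness estimator; thickness-averaged sampling was
   considered and rejected as second-order at 5 mm for these sizes).
2. **Boundary placement** (`boundary_noise_sd_mm`, default 0.6 mm) — one
   draw per scan added to every boundary radius. This is the dominant term:
   it models how edge conspicuity, window/level and contrast phase move the
   *perceived* edge by a fixed physical distance (of order one 0.68 mm
   pixel), so its relative effect scales as 1/r and measurement COV falls
   as objects grow.
3. **In-plane scale** (`scale_noise_sd`, default 0.05) — one fractional
   draw per scan, a scan-wide calibration/contrast effect.
4. **Tracing jitter** (`radial_noise_sd`, default 0.05) — i.i.d. fractional
   noise per vertex. First-order propagation through the shoelace formula
   gives a relative area SD of `2σ/√n_vertices` (the adjacent-term
   covariance halves the naive variance), about 1.3% per slice at the
   defaults — tracing wobble largely cancels out of enclosed area, which is
   why it cannot by itself explain double-digit volume COVs.
5. **Pixel quantization** (`pixel_quantization`, default 0.68 mm =
   350 mm FOV / 512 matrix) — vertices snap to the pixel grid.

### Calibration

The defaults were fixed once, from closed forms, to reproduce the
documented ~18% COV for a 3.4 cm³ object at t = 5 mm. Exhaustive sweep of
the alignment offset gives a 2.3% COV contribution at that size (and only
0.7–4% anywhere in 1–16 cm³ — alignment alone cannot explain the observed
imprecision, and is not even monotone in volume at fixed t). The scale term
contributes `2η = 10%`; the boundary term contributes
`(3π/4)·s/r ≈ 2.36·s/r`, so `s = 0.6 mm` closes the budget:
`sqrt(0.10² + 0.023² + (2.36·0.6/9.33)² + 0.013²) ≈ 0.183`. Because only
the boundary term depends on object size, the model predicts COV falling
from ≈25% at 1 cm³ to ≈13% at 16 cm³ — the inverse precision–volume
relationship — and the test suite verifies both the calibrated level
(median COV within 0.14–0.24 at 3.4 cm³) and the strict decrease of median
COV across 1/2/4/8/16 cm³ spheres.

Reproducibility: every output is a pure function of the `phantom_spec`
including its seed. Per-scan child seeds are drawn from the master stream
up front, so extending a series never perturbs earlier scans; identical
specs produce byte-identical CSV output.

### What the simulator does *not* model

No image-domain physics (no HU values, reconstruction, or noise texture),
no patient motion, no observer learning or fatigue, no contrast-enhancement
differences between scans beyond the scalar scale term, and no true volume
change. Passing simulation tests therefore show that the *analysis chain*
behaves correctly under a plausible noise structure — not that the noise
decomposition is the physically correct one for any particular scanner or
observer. The per-scan boundary/scale decomposition is a construction
validated only against the aggregate COV level and its volume trend.

## Numerical and interface choices

* Zero-area contours are a hard validation error, never a silent 0 cm³
  slice: observable failure over silent bias.
* Stack validation reports (rather than throws) structural problems, and
  warns about probable partial coverage when an outermost contour exceeds
  50% (configurable) of the maximum contour area — scans that clip the
  organ should be excluded from precision series.
* Cohort COVs average per-patient COVs unweighted (not pooled over scans):
  each patient's series is one estimate of the precision, regardless of its
  length.
* The inter-observer statistic reports the absolute pairwise percent
  difference by default (`signed = TRUE` reveals systematic offsets); it is
  symmetric and bounded by 2.
* Paired-organ `r²` matches measurements by scan order within patient.
* The COV–volume trend defaults to a straight line of COV on volume, with
  `form = "log-volume"` as an alternative; with the inverse mechanism above
  neither form is canonical, so the fitted `r²` should be read as
  indicative.
* Display rounding (1 d.p. volumes and percents, half away from zero)
  happens only in the reporting layer; all CSV outputs carry full
  precision next to the display columns.
* Reported series in the test suite use deliberately modest problem sizes —
  e.g. 200 replicate series per phantom size, 13 scans per series (a
  typical serial-CT case load), 0.05 mm rasterization grids — chosen as the
  smallest sizes at which the Monte-Carlo error is far below the effects
  being checked.

## Known limitations

* The star-shaped boundary parameterization cannot represent strongly
  concave cross-sections (e.g. widely separated bilobed lobes); the
  simulator is meant for compact lesion-like shapes.
* Slice-summation volumetry is biased at coarse `t` relative to the true
  volume (that bias is the object of study, not removed).
* No mixed-effects/variance-components repeatability decomposition is
  provided; the package quantifies total test–retest variability only.
* The detectable-change model assumes exchangeable, approximately normal
  measurement errors within a series; heavy-tailed observer blunders would
  inflate both SD and the threshold.
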