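# volprec

Precision of longitudinal volume measurement in clinical CT.

## The problem

Tumor response is increasingly judged by volume rather than by a single
diameter, but a measured volume change on serial CT is only meaningful if it
exceeds the reproducibility of the measurement itself. When a small organ is
hand-outlined slice by slice on routine 5 mm abdominal CT, repeated
measurements of a volumetrically stable structure scatter with a coefficient
of variation (COV) of roughly 18% — so a 10% "shrinkage" of an adrenal-sized
lesion may be nothing but noise. `volprec` is for imaging scientists and
quantitative-imaging methodologists who need to (a) compute slice-summation
volumes from planar contours, (b) quantify test–retest precision from
longitudinal series, (c) derive the minimal statistically detectable change
for a given series, and (d) simulate the whole measurement process with
phantom lesions.

## The methods

* **Slice-summation volumetry.** For contours with areas `A_j` (cm²) on
  slices of thickness `t` (mm), the organ volume is `V = Σ_j A_j · t / 10`
  (cm³). Contour areas come from the shoelace formula on the hand-traced
  polygon.
* **Precision statistics.** For a series of `n` repeated measurements,
  `COV = SD / mean` (sample SD, `n−1` denominator). Cohort COVs average
  per-patient COVs unweighted. Paired organs are compared by the squared
  Pearson correlation `r²` of scan-matched volumes; the COV-versus-volume
  trend is an OLS line (precision improves with object size).
* **Minimal detectable change.** Treating the post-change series as an
  independent, equally noisy series, the smallest fractional volume change
  detectable by a two-sided paired t-test at level `α` is
  `δ = t_{1−α/2, n−1} · √2 · SD / (√n · mean)`, with isotropic linear
  equivalent `(1+δ)^{1/3} − 1`. A 30% RECIST diameter decrease corresponds
  to shrinkage to `0.70³ = 0.343` of the initial volume.
* **Phantom simulation.** Parametric lesions (sphere, ellipsoid, bilobed)
  are "scanned" repeatedly: a uniform slice-grid offset, a per-scan
  boundary-placement error with a fixed length scale (~1 pixel), a per-scan
  fractional scale error, per-vertex tracing jitter, and pixel quantization
  of the traced vertices. Defaults reproduce an ~18% volume COV for a
  3.4 cm³ object at 5 mm slices, falling as the object grows.

## Worked example

Simulate 20 repeated scans of a spherical 3.4 cm³ lesion (18.7 mm diameter)
at 5 mm slice thickness, then ask what volume change those measurements
could actually detect:

```r
library(volprec)

spec   <- phantom_spec("sphere", diameter_mm = 18.7, n_scans = 20, seed = 7)
series <- simulate_longitudinal_series(spec)
s      <- series_summary(series$volume_cm3)
s
#> <precision_summary> n=20  mean=3.62 cm^3  sd=0.75 cm^3  COV=20.6%

min_detectable_volume_change(s$mean, s$sd, s$n, alpha = 0.05)
#> <detectable_change> n=20, mean=3.62 cm^3, sd=0.75 cm^3, alpha=0.05 (independent-noise)
#>   minimal detectable volume change: 13.6%  (linear equivalent 4.3%)

classify_change(0.10, s$cov)
#> [1] "within_precision"
```

Reading: the simulated hand-measurements of a perfectly stable lesion
scatter with a 20.6% COV, so a two-sided paired t-test on 20 scans can only
certify volume changes larger than about 13.6% — and an observed 10% change
is within measurement precision, i.e. not evidence of true growth. Note the
linear equivalent (4.3%) is far smaller than the ~5.3% one-pixel cursor
error on an object this size (`pixel_error_linear_fraction(0.68, 12.8)`),
which is why volumetric assessment is the more robust response metric.

A shell interface covers the same pipeline
(`area`, `volume`, `precision`, `detect`, `simulate`, `report`, `demo`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "volprec.R", package = "volprec"))')" \
  detect --mean 3.4 --sd 0.64 --n 20 --alpha 0.05
#> {"delta_volume":0.12458773100142,"delta_linear":0.0399148509556568,"alpha":0.05,"n":20,"model":"independent-noise"}
```

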