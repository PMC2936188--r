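Package: volprec
Title: Precision of Longitudinal Volume Measurement in Clinical CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the reproducibility (precision) of
    slice-summation tumor and organ volumetry on routine clinical CT.
    Computes volumes from hand-drawn planar contours (sum of ROI area times
    slice thickness), longitudinal precision statistics (coefficient of
    variation, inter-observer percent difference, paired-organ correlation,
    COV-versus-volume trend), the minimal statistically detectable volume
    change for a measurement series under a paired t-test, conversions
    between linear (RECIST-style) and volumetric response criteria, and a
    phantom-lesion simulator that emulates repeated CT scanning with slice
    alignment, boundary-tracing and pixel-quantization noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
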