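Package: tibhip
Title: Time-in-Bed Detection from Hip-Worn Accelerometer Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects time in bed (TiB) from hip-worn tri-axial accelerometer
    recordings at one-minute resolution. Provides signal preparation
    (stationary-epoch autocalibration, per-minute aggregation, cohort
    z-normalization), accelerometer-specific training-time augmentation
    (random cropping, upside-down flipping, time reversal, additive noise),
    a uni/bi-directional LSTM sequence labeller with a subject-level
    cross-validation harness, sliding-window non-wear detection, dual-annotator
    interval quality control via intersection-over-union, and day-level
    evaluation with outlier flagging and Bland-Altman method comparison.
    A synthetic multi-day free-living signal generator makes the whole
    pipeline runnable and testable without any device data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
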