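Package: repwatch
Title: Exercise Recognition and Repetition Counting from Smartwatch Inertial Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for recognizing full-body exercises and
    counting repetitions from raw wrist- and ankle-worn smartwatch inertial
    streams (accelerometer, gyroscope, orientation). Irregularly sampled
    streams are linearly resampled to a uniform 100 Hz grid and stacked into
    an 18-channel matrix; overlapping windows are classified by a small 2-D
    convolutional network whose first layer strides over sensor-axis
    triplets; per-window predictions are fused by majority voting and
    smoothed with per-exercise minimum repetition durations; repetitions are
    counted by a per-exercise binary start-detection network whose output
    sequence is cleaned by mode-based run-length smoothing. Includes a
    seeded synthetic workout generator, subject-grouped cross-validation,
    and the usual counting error metrics (MAE, MRE, error buckets).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
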