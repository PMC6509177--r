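Package: spastr
Title: Quantitative Muscle Spasticity Assessment from Wearable EMG and Gyroscope Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Regression-based quantitative assessment of elbow muscle
    spasticity from one surface-EMG channel and one wrist-worn gyroscope
    recorded during passive stretches. Implements zero-phase Butterworth
    preprocessing with automated movement/EMG-onset detection, the lambda
    model (dynamic stretch reflex thresholds regressed on stretch velocity to
    a tonic threshold, TSRT), a constant-jerk kinematic reconstruction with
    curve-similarity and median-frequency biomarkers, and calibration of the
    biomarkers to the modified Ashworth scale by linear regression,
    multivariate regression and epsilon-insensitive support vector regression,
    evaluated with leave-one-out cross-validation. A seeded synthetic
    passive-stretch simulator generates cohorts with the statistical structure
    the two models assume, so the whole chain is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    kernlab,
    pracma,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
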