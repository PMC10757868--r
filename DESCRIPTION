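Package: vpmrecal
Title: Validation and Recalibration of the Vienna Prediction Model for
    Recurrent Venous Thromboembolism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for externally validating and updating the Vienna
    Prediction Model (VPM), a Cox-model based score that predicts recurrence
    of unprovoked venous thromboembolism from sex, index thrombosis site and
    D-dimer. Provides per-patient risk scoring against a configurable model
    definition, Kaplan-Meier and actuarial estimation of cumulative
    recurrence incidence, one-sample threshold z-tests, calibration slope,
    observed/expected event ratios, Uno's inverse-probability-of-censoring
    weighted concordance, Breslow baseline-hazard recalibration with
    bootstrap percentile confidence bands, Harrell optimism-corrected
    internal validation, a piecewise-exponential synthetic cohort generator
    matched to published cohort summaries, and a simulation-based power
    calculation for threshold designs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
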