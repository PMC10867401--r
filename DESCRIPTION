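Package: plantarpress
Title: Smart-Insole Plantar Pressure Analytics with a Segmentation-Assisted 1D CNN
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for 8-channel capacitive smart-insole recordings of
    plantar pressure. Provides a seeded synthetic gait generator (standing, walking,
    running and jumping in rested and fatigued states), a piecewise-linear
    capacitance/pressure calibration model, cubic B-spline surface interpolation of
    the discrete sensor readings to a full-foot pressure map with static pronation
    classification, long-term usage statistics (pressure-zone occupancy, high-pressure
    dwell times, activity and energy-expenditure reports), a sliding-window
    segmentation pipeline feeding a one-dimensional convolutional neural network for
    posture and exercise-fatigue recognition, and a streaming rule-based engine for
    foot-health alerts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    pracma,
    Rcpp,
    splines,
    stats,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
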