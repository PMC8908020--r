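Package: gaitcoreset
Title: Discriminative Core Sets of Kinematic Gait Variables After Stroke
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies small, discriminative core sets of kinematic gait
    variables that separate persons post-stroke from non-disabled controls.
    Implements the full analysis pipeline: simulation of two-group gait
    cohorts at the variable-table and joint-angle-curve level, extraction of
    spatiotemporal parameters, ranges of motion, side-to-side symmetry
    indices, body-inclination angles and control-referenced gait deviation
    scores (Gait Profile Score, Arm Posture Score, Gait Deviation Index)
    from cycle-normalized curves, covariate-adjusted linear-model screening
    of candidate variables, exhaustive enumeration of 1-4 variable subsets
    scored by leave-one-out cross-validated logistic-regression
    misclassification rate with separation-tolerant fitting, confusion-matrix
    reporting, and grouped Spearman correlation matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
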