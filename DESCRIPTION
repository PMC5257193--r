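Package: mahanorm
Title: Normative Trajectories and Mahalanobis Deviation Scores for
    Longitudinal Brain Microstructure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Normative modelling of regional white-matter microstructure in
    accelerated longitudinal designs. Fits penalized-spline growth curves with
    subject random intercepts to typically developing control data, scores
    every individual's multivariate deviation from the normative curves with
    the Mahalanobis distance (with leave-one-out handling for controls and
    regularized residual-covariance estimation), computes univariate standard
    scores, and compares deviation distributions between groups via
    Bhattacharyya overlap, t/F statistics, exceedance fractions and phenotype
    correlations. Includes a synthetic-cohort generator with full ground truth
    for calibration and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    mgcv,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
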