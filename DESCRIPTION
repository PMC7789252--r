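Package: bvckmr
Title: Bayesian Kernel Machine Regression for Metal Mixtures and Child
    Blood Pressure Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Longitudinal Bayesian varying-coefficient kernel machine
    regression (BVCKMR) for repeated blood-pressure measures and
    probit Bayesian kernel machine regression (BKMR) with hierarchical
    spike-and-slab variable selection for binary elevated-blood-pressure
    outcomes, applied to prenatal urinary metal-mixture exposures.
    Includes specific-gravity dilution adjustment, log2 standardisation
    and outlier screening of urinary biomarkers, static and
    percentile-based paediatric blood-pressure classifiers, posterior
    summaries (interquartile-range contrasts, exposure-response curves,
    bivariate interaction surfaces, inflection points, posterior
    inclusion probabilities), confirmatory penalised-spline single-metal
    fits, and a calibrated synthetic cohort generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    mgcv,
    yaml,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
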