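Package: phenoscreen
Title: Digital Behavioral Phenotyping for Early Autism Screening
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analyzing tablet-based digital phenotyping sessions
    used in early autism screening. Computes 23 app-derived behavioral
    variables (gaze, facing forward, facial dynamics complexity, head
    movement, response to name, blink rate and touch-based visual-motor
    skills) from session signals; trains an ensemble of gradient-boosted
    tree classifiers with stratified cross-validation, class weighting and
    out-of-range missing-value encoding; derives per-child prediction
    confidence scores, exact Shapley attributions with a missingness
    decomposition, and administration quality scores; and evaluates
    diagnostic accuracy with ROC/AUC (Hanley-McNeil standard errors),
    Youden operating points and prevalence-calibrated predictive values.
    Includes a synthetic cohort and session generator so the full pipeline
    is testable without access-restricted study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
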