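Package: shapdrift
Title: Explainability-Based Drift Surveillance for Clinical Risk Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monitors deployed clinical risk models for data drift and concept
    drift using exact Shapley attributions of gradient-boosted tree ensembles.
    Per-attendance attributions are normalised into importance shares that are
    invariant to changes in the outcome base rate, binned weekly with bootstrap
    confidence intervals, and combined with time-binned AUROC tracking into a
    decision rule that separates data drift from suspected concept drift.
    Includes a synthetic emergency-department attendance simulator with a known
    logistic admission mechanism and injectable drift events (covariate shift,
    prevalence shift, missingness shift, category emergence, concept shift) for
    end-to-end validation of the surveillance pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    xgboost
LinkingTo:
    Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
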