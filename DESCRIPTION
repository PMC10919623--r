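Package: wearsite
Title: Multi-Site Accelerometry Simulation and Wear-Site-Agnostic Activity
    Intensity Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates multi-wear-site (hip, wrist, chest) triaxial
    accelerometry at 100 Hz together with indirect-calorimetry oxygen-uptake
    series for adult and child cohorts; derives metabolic-equivalent (MET)
    ground truth for four-level physical-activity intensity; emulates
    ActiGraph-style activity counts and classical hip cut-point
    classification, including deliberate wear-site misspecification; and
    trains LSTM and Bi-LSTM sequence classifiers on raw 1-second acceleration
    windows for wear-site detection and wear-site-agnostic intensity
    classification, with optional anthropometric covariates. The recurrent
    networks are implemented natively with 'RcppArmadillo'.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    signal,
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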