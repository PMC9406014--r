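Package: vmdcal
Title: Multiscale Spectral Calibration by Variational Mode Decomposition and
    Weighted Support Vector Regression Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multivariate calibration of adulterant content from UV-Vis and
    near-infrared spectra. Each spectrum is decomposed into narrow-band mode
    components by variational mode decomposition (ADMM in the frequency
    domain), one least-squares support vector regression sub-model is fitted
    per recombined mode matrix, and sub-model predictions are combined with
    weights proportional to the inverse fourth power of each sub-model's
    cross-validation error. Includes Kennard-Stone sample partitioning,
    particle swarm hyperparameter search, a PLS baseline with Monte Carlo
    cross-validation plus F-test rank selection, prediction-set metrics, and
    a synthetic mixture-spectra generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
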