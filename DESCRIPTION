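Package: coxL12
Title: Adaptive L1/2 Shooting Regularization for Cox Proportional
    Hazards Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Variable selection and survival prediction for
    high-dimensional censored data under the Cox proportional hazards
    model.  Implements the adaptive L1/2 shooting algorithm, a
    coordinate-wise ("shooting") method that optimizes an iteratively
    linearized partial likelihood under the nonconvex half-power penalty
    via reweighted L1 surrogates, together with Lasso and adaptive-Lasso
    comparators, cross-validated partial likelihood (CVPL) tuning, a
    Gompertz-baseline survival simulator, and evaluation tools
    (Kaplan-Meier curves, log-rank tests, Breslow baseline hazards, and
    the IPCW integrated Brier score).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    survival,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
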