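Package: baclopk
Title: Population Pharmacokinetics of High-Dose Oral Baclofen
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Nonlinear mixed-effects analysis of sparse oral baclofen
    concentration data at daily doses of 30 to 300 mg. Implements a
    one-compartment first-order absorption/elimination structural model with
    multiple-dose superposition, first-order conditional estimation with
    interaction (FOCE-I) of fixed effects, between-subject variances and an
    exponential residual error model, stepwise covariate selection on
    likelihood-ratio objective-function thresholds, nonparametric bootstrap
    confidence intervals, normalized prediction distribution errors (NPDE),
    prediction-corrected visual predictive checks (pcVPC), and a synthetic
    sparse-sampling study generator reproducing a four-dose-group steady-state
    trial design so the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    rlang,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    deSolve,
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
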