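Package: salbupk
Title: Population Pharmacokinetics of Oral Salbutamol from Whole-Body
    Physiological Simulations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A fully in-silico population-pharmacokinetic (popPK) workflow for
    oral salbutamol. A whole-body perfusion-limited physiologically based
    pharmacokinetic (PBPK) simulator with a compartmental absorption and
    transit (CAT) gut model generates plasma concentration-time data for a
    virtual patient cohort; a nonlinear mixed-effects pipeline
    (two-compartment disposition with transit-compartment absorption,
    stochastic approximation EM estimation, importance-sampling likelihood,
    stepwise and correlation-based covariate selection, and VPC/NPDE/GOF
    diagnostics) recovers population parameters and covariate effects from
    the simulated data. Non-compartmental analysis and fold-error
    validation utilities are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
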