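Package: fvcjoint
Title: Joint Models Linking FVC Decline to Hospitalisation and Death in
    Systemic Sclerosis ILD
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Shared-parameter joint models for forced vital capacity (FVC,
    percent predicted) trajectories and time to first hospitalisation or
    death in interstitial lung disease trials.  The longitudinal sub-model
    is a normal linear mixed-effects model with subject-specific intercepts
    and slopes; the time-to-event sub-model is a piecewise-exponential
    hazard stratified by anti-topoisomerase antibody status; the two are
    linked through the subject's estimated annual rate of FVC decline or
    the estimated current FVC value.  Includes maximum-likelihood
    estimation via adaptive Gauss-Hermite quadrature, Wald inference,
    hazard-ratio reporting for k-unit declines, risk curves, a calibrated
    two-arm trial simulator, and parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    nlme,
    survival,
    optparse
Config/testthat/edition: 3
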