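Package: algaetox
Title: Concentration-Response Analysis for Microalgal Herbicide Bioassays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for 72-hour algal growth-inhibition bioassays
    with PAM-fluorometry endpoints. Computes specific growth rates, effective
    quantum yields, percent inhibition and time-weighted-average exposure
    concentrations from long-format replicate records; applies assay validity
    criteria (control growth, control CV, pH drift); fits four-parameter
    logistic concentration-response curves with multi-start least squares and
    derives ECx values with bootstrap confidence intervals; estimates Bayesian
    no-effect concentrations (NEC) with a piecewise-exponential threshold model
    sampled by adaptive Metropolis-within-Gibbs MCMC; summarises relative
    potencies, endpoint-sensitivity ratios and regressions; and generates
    synthetic bioassays with known truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
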