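Package: chronophase
Title: Bayesian Chronological Modelling of Radiocarbon Dates with Uniform
    Phase Models and MCMC Density Summaries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building calendar-age chronologies from radiocarbon
    determinations. Calibrates conventional radiocarbon ages against
    piecewise-linear calibration curves (including marine reservoir
    corrections and uniform hemispheric curve mixing), fits uniform phase
    models with start/end boundaries and Student-t outlier down-weighting by
    Metropolis-within-Gibbs sampling, summarises sets of related dates with
    an MCMC kernel density model, and runs a multi-site timeline pipeline
    that estimates the start of human activity per category (geographic
    province, lithic technology, altitude, megafauna exploitation) relative
    to the Antarctic Cold Reversal and Younger Dryas intervals. Includes a
    synthetic-data generator with known ground truth for end-to-end testing.
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
RoxygenNote: 7.3.3
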