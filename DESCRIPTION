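Package: iprs
Title: Interaction-Aware Polygenic Risk Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction and evaluation of polygenic risk scores that carry
    per-variant gene-environment interaction weights (iPRS) alongside the
    traditional marginal-weight PRS baseline. Reads PLINK 1 binary genotypes,
    applies standard variant and sample quality control including an exact
    Hardy-Weinberg test, runs per-variant marginal and interaction logistic
    scans, builds risk-allele-flipped scores, fits two-stage logistic
    prediction models under stratified k-fold cross-validation, and evaluates
    them by AUC with the DeLong test, percentile risk stratification with a
    prevalence chi-square comparison, Brier score with bootstrap confidence
    intervals, calibration curves, Spiegelhalter's z and Cox recalibration
    slope and intercept. Includes sparse and polygenic case-control phenotype
    simulators with binomial genotypes and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
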