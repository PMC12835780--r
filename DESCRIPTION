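Package: fairsurv
Title: Fairness-Aware Deep Cox Proportional Hazards Models for
    Censored Survival Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for training and auditing deep Cox proportional
    hazards models on multi-group right-censored survival data. Provides
    a feed-forward log-hazard network trained by stochastic gradient
    descent under three objectives: the standard negative Cox partial
    log-likelihood, a fairness penalty that shrinks group differences in
    mean predicted log-hazard, and a group distributionally robust
    objective that minimises the worst group's partial log-likelihood
    (with an augmented full-cohort group). Includes Breslow baseline
    hazard recovery and absolute survival curves, a fairness evaluation
    suite (overall, cross-group and within-group concordance, IPCW
    integrated Brier score, integrated calibration index, bootstrap
    confidence intervals), risk stratification with per-group
    Kaplan-Meier curves and pairwise log-rank audits, and a synthetic
    multi-group cohort generator with controllable group imbalance and
    group-dependent hazards.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
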