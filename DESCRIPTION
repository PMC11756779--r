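Package: synarm
Title: Synthetic External Control Arms for Survival Trials
Version: 0.1.0
Authors@R:
    person("Registry", "Synthetics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for replacing the empirical external control arm of a
    single-arm clinical trial with a synthetic one. Provides reversible
    quantile-bin generalization with differentially private truncated-normal
    reversal (Laplace mechanism), baseline and differentially private
    Bayesian-network (PrivBayes-style) data generators behind a common
    fit/sample contract, a resemblance / survival-utility / privacy metric
    suite (Kolmogorov-Smirnov, Jensen-Shannon, Cox beta distance, median and
    full survival-curve distances, spline-based predicted survival distance,
    CAP, detection AUROC, DCR, NNDR), rank-based generator selection, a
    simulated two-arm oncology cohort for end-to-end testing, and a hybrid-arm
    treatment-effect analysis with bootstrapped Cox hazard ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    truncnorm,
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
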