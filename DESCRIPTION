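Package: rrtccw
Title: Clone-Censor-Weight Emulation of RRT Initiation Timing Trials in Acute Kidney Injury
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to emulate target trials of early versus delayed initiation
    of renal replacement therapy (RRT) in ICU patients with acute kidney injury
    from longitudinal (hourly) electronic health record data. Implements
    KDIGO creatinine staging, hour-level eligibility screening, the
    clone-censor-weight design with a configurable grace period, pooled
    logistic treatment-hazard models with stabilized inverse-probability
    weights, weighted Cox and Weibull accelerated failure time outcome models
    with cluster-robust errors, doubly robust (augmented IPW) fixed-horizon
    risk estimation, and covariate balance and collinearity diagnostics.
    Ships a synthetic ICU cohort generator with confounded treatment
    initiation and known counterfactual ground truth for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    splines,
    stats,
    utils,
    jsonlite
Suggests:
    arrow,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
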