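Package: gestgfr
Title: Gestational Serum Creatinine Reference Intervals and Hyperfiltration-Based eGFR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds gestational-week-specific serum creatinine (SCr) reference
    intervals for pregnancy by mean-of-two bootstrap resampling with Gaussian
    acceptance criteria and CLSI-style coverage verification, smooths the
    period-level percentiles into week-level curves by repeated k-fold
    cross-validated polynomial degree selection, and converts SCr to an
    absolute (non body-surface-area indexed) estimated glomerular filtration
    rate through a renal hyperfiltration formula anchored at the
    pre-implantation baseline. Includes a synthetic cohort generator with a
    closed-form quantile oracle, verification against an external percentile
    table, and clinical result flagging.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
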