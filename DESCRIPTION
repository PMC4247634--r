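Package: possumval
Title: External Validation and Recalibration of POSSUM-Family Surgical Risk Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Audit toolkit for POSSUM-family surgical mortality scores. Implements
    the POSSUM, P-POSSUM and S-POSSUM logistic mortality equations and the full
    external-validation pipeline used in surgical audit: ROC/AUC discrimination,
    calibration by equal-width or equal-expected-deaths risk bands with
    Hosmer-Lemeshow components and totals, observed-to-expected mortality ratios
    with exact Poisson confidence intervals, and logistic recalibration by
    Newton-Raphson maximum likelihood. Includes a seeded synthetic surgical-cohort
    simulator with a controllable logit-scale calibration distortion so the whole
    pipeline can be exercised and tested without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
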