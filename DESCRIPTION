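Package: stentstrat
Title: Subgroup-Specific Risk Stratification for Coronary Stent and Bypass Treatment Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage stratification of coronary-artery-disease patients for
    revascularization. Subgroup-specific classification trees with
    l2-regularized logistic-regression leaves predict restenosis risk under
    bare-metal stents and hazardous-event risk under drug-eluting stents, and
    are cascaded into a per-patient treatment suggestion (BMS, DES or CABG).
    Includes closed-form effectiveness and per-patient cost estimators for the
    proposed and baseline workflows, a stent-cost sensitivity grid, a repeated
    k-fold cross-validation scheme with percentile confidence intervals, and a
    synthetic cohort generator with planted subgroup-heterogeneous outcome
    models for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    glmnet,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
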