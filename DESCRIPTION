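Package: ipiadx
Title: Diagnostic Evaluation of Immunoprecipitation-Enhanced Plasma
    Alzheimer Biomarkers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Statistical machinery for comparing paired plasma biomarker
    assays (direct measurement versus pre-analytical immunoprecipitation
    eluate) for blood-based Alzheimer's disease diagnostics. Implements
    robust effect-size estimation (relative median/mean differences,
    Cohen's d), a 0.632-bootstrap test for differences of paired effect
    sizes, empirical ROC analysis with DeLong variance and paired AUC
    comparison, Youden-point classification statistics, cross-validated
    logistic-regression ROC, two-component equal-variance Gaussian
    mixture cutpoints, Deming errors-in-variables regression, and a
    calibrated lognormal-copula cohort simulator for the plasma
    Abeta1-42/1-40 ratio and pTau181 panel.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
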