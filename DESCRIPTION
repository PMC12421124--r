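Package: nodulestrat
Title: Size and Risk Threshold Stratification of Solid Pulmonary Nodules in
    CT Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for evaluating nodule management protocols applied to
    solid pulmonary nodules found at baseline low-dose CT in lung cancer
    screening. Reduces multi-nodule screening cohorts to per-participant
    index nodules, applies volumetric and diameter rule-out/rule-in size
    thresholds with Brock (PanCan) malignancy-risk gating, and computes the
    associated diagnostic accuracy statistics: sensitivity, specificity,
    predictive values with exact binomial confidence intervals, crude risks,
    Pearson chi-squared and McNemar comparisons, univariable logistic odds
    ratios per unit size, empirical ROC curves with DeLong AUC comparison
    and Youden-optimal cut-points, and a weighted net-benefit statistic with
    participant-level bootstrap confidence intervals. Includes a synthetic
    screening-cohort generator and an exact reconstruction of a
    participant-level fixture from published cumulative marginal counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
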