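Package: urovaf
Title: Error-Suppressed Hotspot Mutation Detection in Urine Cell-Pellet DNA
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detection of bladder cancer from urine cell-pellet DNA using
    non-coding hotspot mutations. Implements UMI (unique molecular identifier)
    consensus collapsing of deep-sequencing reads for error suppression,
    quality-filtered variant allele frequency (VAF) quantification over a
    user-supplied hotspot panel, a specificity-calibrated maximum-VAF
    classifier, and the downstream diagnostic statistics: sensitivity and
    specificity with exact (Clopper-Pearson) confidence intervals, ROC curves
    and AUC, stage/grade-stratified detection tables, age-band false-positive
    rates, and relative risk of future recurrence in a surveillance setting.
    A synthetic cohort and read-level simulator with the same statistical
    structure allows every stage to be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
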