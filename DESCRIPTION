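Package: actidep
Title: Digital Biomarkers and Depression Screening from Consumer Wearable Streams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for screening depressive symptoms from consumer-wearable
    time series. Provides a synthetic cohort simulator (minute-level steps and
    energy expenditure, 5-second heart rate, 30-second sleep stages, paired
    PHQ-9 assessments, plantable group effects), heart-rate-based completeness
    and quality control, extraction of activity, sleep, circadian-rhythm
    (extended cosinor and nonparametric) and heart-rate digital biomarkers,
    Spearman/FDR association screening with covariate-adjusted hierarchical
    regression, and repeated k-fold cross-validated gradient-boosted (DART)
    models of depression risk under several PHQ-9 cutoff rules, including
    contrasted subsampling.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    data.table,
    minpack.lm,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
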