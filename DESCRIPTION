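Package: growthscreen
Title: Screening Performance of Third-Trimester Fetal Biometry for
    Small-for-Gestational-Age Infants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for evaluating selective versus universal
    third-trimester ultrasonographic screening for small-for-gestational-age
    (SGA) infants and fetal growth restriction. Implements Hadlock estimated
    fetal weight and percentile standards behind a pluggable registry,
    gestational-age-adjusted Z-scores and abdominal-circumference growth
    velocity, screen classification rules, paired diagnostic-accuracy
    comparison (McNemar, generalized score tests for predictive values,
    regression-based likelihood-ratio comparison, ROC/DeLong), stratified
    relative-risk analysis with Mantel-Haenszel-style interaction tests, and
    a seeded synthetic cohort generator calibrated to the statistical
    structure of a nulliparous screening cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    pROC,
    rlang
Suggests:
    withr,
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
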