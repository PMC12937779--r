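Package: fhrrisk
Title: Antepartum Fetal Heart Rate Feature Extraction and Preterm Risk
    Stratification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates antepartum cardiotocography (fetal heart rate) traces
    with planted ground truth, extracts the seven clinically validated
    Dawes-Redman style features (basal heart rate, accelerations,
    decelerations, most lost beats, short-term variation, minutes of high and
    low variation), applies plausibility and cohort-construction filters,
    builds propensity-score matched and stratified train/validation datasets,
    trains and compares six classifier families with balanced cross-validation
    and Bayesian hyperparameter optimisation, and evaluates discrimination,
    calibration, operating thresholds and decision-curve net benefit for
    preterm adverse-outcome risk stratification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    e1071,
    rpart,
    ranger,
    glmnet,
    xgboost,
    lhs
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
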