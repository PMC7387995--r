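Package: scolioscreen
Title: Risk Prediction for Adolescent Idiopathic Scoliosis from School
    Screening Postural Signs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating logistic-regression risk
    prediction models for adolescent idiopathic scoliosis (AIS) from
    school-screening records of postural signs (shoulder-height difference,
    scapular tilt, lumbar concave, pelvic tilt, sagittal-profile flags, and
    scoliometer angle-of-trunk-rotation readings). Provides a seeded
    case-control cohort simulator calibrated to published screening
    prevalences, contingency-table descriptive statistics, univariate and
    multivariate odds-ratio estimation, closed-form rank AUC for grouped
    categorical predictors with Hanley-McNeil confidence intervals,
    coefficient re-weighting of logistic models by adjusted odds ratio
    and/or AUC, and a stratified train/test evaluation protocol reporting
    sensitivity, specificity, Youden's index, predictive values and total
    accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
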