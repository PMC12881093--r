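Package: ugmir
Title: Updated Glucose Management Indicator and CGM-Based Retinopathy Risk Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating HbA1c from continuous glucose monitoring
    (CGM) data through the updated glucose management indicator (uGMI), a
    reciprocal-form estimate derived from steady-state glycation kinetics,
    together with the consensus CGM metric suite (mean glucose, SD, CV, time
    in range, time in tight range, time above/below range).  Includes a
    seeded synthetic case-control cohort generator with an individual
    glycation gap, and the statistical pipeline used to compare glycemic
    biomarkers against a binary complication outcome: mutual-information
    ranking, minimum-redundancy maximum-relevance selection, recursive
    feature elimination, ROC and cumulative-rate curves, quintile risk
    tables, fixed-threshold decision trees, and cross-validated comparison
    of logistic-regression and random-forest classifiers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    randomForest,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
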