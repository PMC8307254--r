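Package: qeegstroke
Title: Task-Induced Quantitative EEG Biomarkers for Ischemic Stroke
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end quantitative EEG (qEEG) analysis pipeline for
    task-induced stroke biomarkers: synthetic multichannel EEG cohort
    simulation with group- and task-dependent band structure, hemispheric
    asymmetry and ocular/muscular artifacts; preprocessing (notch and
    band-pass filtering, reference-channel artifact regression, fixed 10-s
    epoching); Welch power spectral density estimation and band-power
    features (absolute and relative power, baseline-relative change,
    spectral summary statistics); stroke biomarkers (delta-alpha ratio,
    delta-theta ratio, (delta+theta)/(alpha+beta) ratio, pairwise-derived
    brain symmetry index, hemispheric band-power asymmetry); Levene-gated
    group comparisons and chi-square feature-importance ranking; and a
    stroke-versus-control classification harness (decision tree, RBF SVM,
    logistic regression, random forest) with a confusion-matrix metric
    panel including AUC and Gini.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    car,
    e1071,
    rpart,
    randomForest,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
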