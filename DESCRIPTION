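Package: febrimark
Title: Phenotyping Febrile Children and Evaluating Biomarkers of Bacterial Infection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A rule engine assigning febrile children an eleven-category
    diagnostic phenotype on the bacterial-to-viral spectrum (the PERFORM
    classification) and the conventional dichotomous serious-bacterial-infection
    (SBI) label, together with the downstream biomarker-evaluation pipeline:
    per-category median/IQR summaries, rank and correlation tests, ROC/AUC with
    DeLong confidence intervals, a combined restricted-cubic-spline logistic
    model over procalcitonin, NGAL and resistin, and random-effects
    meta-analysis of study-level AUCs with heterogeneity statistics and forest
    plots. Includes a synthetic-cohort generator emulating the category mix,
    log-normal biomarker distributions and CRP coupling of five published
    pediatric cohorts, so the whole pipeline is testable end to end without
    patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pROC,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    metafor,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
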