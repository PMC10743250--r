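Package: msnsat
Title: Mortality Risk Scoring and Survival Analysis for Outborn Neonates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes the Sick Neonatal Score (SNS) and the Modified
    SNS-Admission Time score (MSNS-AT) for outborn neonates from admission
    vital signs, gestational age, birth weight and time from birth to
    admission, and runs the full statistical pipeline used to evaluate such
    scores: two-by-two odds ratios with Woolf confidence intervals, Pearson
    chi-square and Mann-Whitney U comparisons, ROC curves with
    Youden-optimal cut-offs, Kaplan-Meier curves with log-rank tests, Cox
    proportional-hazards models with Breslow tie handling, and
    hazard-probability AUC model comparison. Includes a calibrated
    synthetic-cohort generator so every stage is testable without
    patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
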