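Package: actbenefit
Title: Predicting Benefit from 5-Fluorouracil-Based Adjuvant Chemotherapy
    in Stage II-III Colorectal Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and validates gene-expression models of who benefits
    from 5-fluorouracil-based adjuvant chemotherapy (ACT) after curative
    surgery for stage II-III colorectal cancer.  Patients are labelled
    ACT-benefit or ACT-futile from their treatment and three-year
    relapse-free survival, candidate genes are screened by Wilcoxon
    rank-sum tests, and a genetic algorithm selects a gene subset for a
    radial-basis-function support vector machine scored by cross-validated
    AUC.  Subpopulation treatment effect pattern plots (STEPP) over the
    calibrated predictive scores determine a benefit cutoff, which is then
    validated with Kaplan-Meier curves, log-rank tests, Cox interaction
    models and propensity-score matched sensitivity analyses.  A synthetic
    cohort generator with planted treatment-modifying genes provides a
    fully reproducible test surface, and a rank-based gene-pair (REO)
    classifier is included as a comparator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    limma,
    stats,
    survival,
    sva,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
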