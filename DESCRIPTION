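Package: ihcsurv
Title: Immunohistochemistry Biomarker Scoring, Cut-Point Stability and
    Survival Analysis for Early Breast Cancer Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for prognostic-biomarker studies on patient-level
    immunohistochemistry (IHC) cohorts: semiquantitative scoring
    (immunoreactive score and H-score), five-group immunophenotype
    classification of early breast cancer (luminal A/B, luminal-HER2,
    HER2-enriched, triple-negative), stability-validated biomarker
    cut-point selection via repeated stratified train/validation splits,
    combined-biomarker survival analysis (Kaplan-Meier, log-rank, Cox
    proportional hazards with interaction tests), and multiple
    correspondence analysis of dichotomized markers.  Includes a
    Gaussian-copula synthetic-cohort generator with proportional-hazards
    event times so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    survival,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
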