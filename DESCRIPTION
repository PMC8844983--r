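Package: dxconcord
Title: Diagnostic Concordance of Symptom-Checker Suggestions with Clinician ICD-10 Diagnoses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Evaluates app-based symptom checkers against multi-diagnosis
    clinician records. Implements rule-based ICD-10 matching of ranked
    condition suggestions (4-digit default with enumerated 3-digit and
    cross-code equivalences), top-1/top-5 percent agreement with
    Agresti-Coull confidence intervals, patient-level contingency
    statistics and Gwet's first-order agreement coefficient (AC1) per
    disorder category, System Usability Scale scoring with benchmark
    labels, and a reproducible synthetic-cohort generator for testing and
    parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
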