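Package: eprotriage
Title: Symptom-Questionnaire Triage and Alert Evaluation for Remote
    Monitoring of Immunotherapy Toxicity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements an 11-item graded symptom questionnaire for melanoma
    patients on immune checkpoint inhibitors, the green/orange/red triage
    scoring rule that converts weekly patient-reported grades into nurse
    alerts with response-deadline semantics, and a retrospective evaluation
    framework that links alerts to immune-related adverse events (IrAEs),
    builds mixed-unit confusion counts, and computes sensitivity,
    specificity, and predictive values with Wilson confidence intervals.
    A seeded cohort simulator generates synthetic patients, questionnaires,
    IrAE registries, and visit schedules with ground-truth annotations so
    the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
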