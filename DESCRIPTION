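Package: triagecheck
Title: Concordance and Safety Analysis of Symptom-Checker Triage Against
    Nurse Triage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for validating electronic symptom-checker (ESC) triage
    against a nurse gold standard on an ordinal urgency scale. Classifies
    paired (nurse, checker) assessments into five match/safety categories,
    computes diagnostic-accuracy statistics (sensitivity, specificity,
    positive and negative predictive values, Matthews correlation
    coefficient) with exact Clopper-Pearson binomial confidence intervals,
    recovers integer confusion matrices consistent with published summary
    statistics, and generates seeded synthetic study cohorts so the whole
    pipeline is testable without raw patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
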