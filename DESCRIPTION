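Package: itqcc
Title: Clinical-Check Gated Scoring of the International Trauma Questionnaire
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Respondent-level ICD-11 PTSD and Complex PTSD (CPTSD)
    diagnostic scoring for the International Trauma Questionnaire (ITQ),
    with and without "clinical check" gating (the ITQ-CC), together with
    the paired statistics used to evaluate the checks (percentage
    decreases, McNemar's Z-test with and without continuity correction,
    Cronbach's alpha, prevalence sample-size planning), a synthetic-cohort
    generator built on a latent-trait graded-response model with a
    true-symptom/false-positive endorsement mixture, and an end-to-end
    pipeline that scores cohorts, builds endorsement summary tables at the
    symptom, cluster and disorder levels, and verifies the derived columns
    of published summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
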