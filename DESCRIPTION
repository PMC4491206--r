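Package: opitox
Title: Claims-Based Identification and Validation of Serious Opioid Toxicity in Children
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for phenotyping serious opioid toxicity in
    pediatric administrative claims. Screens emergency-department, inpatient
    and death records for ICD-9-CM poisoning, adverse-effect and
    CNS/respiratory symptom codes within prescription-anchored risk windows
    (fill date through 14 days after the end of days of supply), encodes a
    structured chart-adjudication rule engine (definite/probable, possible,
    excluded; severity; exposure circumstances), and computes the validation
    statistics for such algorithms: stratified positive predictive values
    with exact binomial confidence intervals, percent agreement and Cohen's
    kappa. Ships a synthetic claims generator with planted ground truth so
    the whole pipeline is testable end-to-end without access to real
    Medicaid data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
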