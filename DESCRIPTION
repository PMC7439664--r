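Package: dlicdss
Title: Drug-Laboratory Interaction Decision Support for Kidney Transplant Medications
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A rule-engine library and command-line tool for detecting
    drug-laboratory interactions (DLIs) in kidney-transplant outpatient
    prescribing. Provides physiologic calculators (Cockcroft-Gault creatinine
    clearance, Hume lean body mass, Child-Pugh score, two-tier hepatic
    impairment classification), a declarative YAML/JSON knowledge base of
    renal, hepatic, pregnancy and lab-monitoring rules seeded with guidance
    for eight high-volume transplant medications, an evaluation engine that
    emits severity-graded, colour-coded, patient-specific alerts with an
    interruptive/informational display contract, an append-only alert audit
    log with refill-reappearance and pregnancy-expiry semantics, and a
    synthetic cohort generator (boundary-crossing fixture patients and
    profile-matched random cohorts) so the whole pipeline is testable without
    any real patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
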