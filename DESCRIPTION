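Package: trialscreen
Title: Rule-Based Clinical Trial Eligibility Screening from Electronic
    Medical Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-testable clinical trial eligibility screening pipeline:
    a text DSL and schema-versioned file format for machine-readable
    eligibility rules (lab thresholds, ratio-to-control labs, medical
    concepts with document-type and temporal constraints, logical
    combinators), a deterministic lexicon-based clinical concept tagger
    with concept unique identifier (CUI) assignment, semantic-type
    filtering and trigger-scope negation detection, a three-valued
    (met / not met / unknown) inference engine producing evidence-linked
    per-criterion verdicts, checklist report rendering with in-text
    concept highlighting, extraction and scoring metrics (precision /
    recall / F1 against gold spans, checklist accuracy, NASA-TLX, SUS),
    and a seeded synthetic electronic medical record generator that
    plants facts with known ground truth so every stage can be validated
    without patient data.
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
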