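Package: edlos
Title: Hospital Length-of-Stay Prediction from Structured and Unstructured
    Emergency-Department Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An end-to-end pipeline for comparing hospital length-of-stay
    (LOS) classifiers built from structured emergency-department (ED) data
    (triage codes, ICD-10 diagnoses) against classifiers built from clinical
    concepts extracted from free-text ED notes. Implements dictionary-based
    concept extraction restricted to patient-centric affirmative sentences,
    a symmetric relevance frequency (srf) filter for high-prevalence
    concepts, hierarchical ICD-10 code roll-up, an ED short-term activity
    index, random-forest models tuned by random search with cross-validation,
    and a deterministic synthetic EHR cohort generator for validating the
    whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
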