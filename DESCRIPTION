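Package: clinconex
Title: Ensemble Clinical Concept Extraction with Weighted API Integration
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A lightweight framework for clinical concept extraction that
    treats named-entity recognition backends as pluggable extractors and
    integrates their outputs with a double weight system: a term-similarity
    weight computed from ranked standardized-code matches merges equivalent
    mentions across extractors, and a cumulative extractor-reliability
    weight decides which merged entities are accepted. Includes NegEx-style
    negation filtering, UMLS-style top-10 concept normalization against a
    local lexicon, precision/recall/F1 evaluation with hyperparameter grid
    tuning, and a synthetic-corpus generator so the whole pipeline runs
    offline against deterministic mock extractors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
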