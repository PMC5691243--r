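Package: crtool
Title: Assessment Core for Concept-Map Based Clinical Reasoning Training
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores learners' illness-script concept maps against staged
    expert reference maps using a MeSH-like hierarchical vocabulary.
    Final diagnoses earn distance-based partial credit in the term tree,
    summary statements are rated by a semantic-qualifier rubric, and five
    rule-based detectors (premature closure, availability, confirmation,
    representativeness, base-rate neglect) explain mismatched final
    diagnoses. Per-session scores are clustered along a clinical reasoning
    process model and assembled into learner dashboard data with peer
    comparison. Includes deterministic generators for toy vocabularies,
    expert cases and simulated learner sessions, JSON bundle I/O with
    validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2,
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
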