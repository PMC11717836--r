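Package: cigsim
Title: Simulation and Learner Verification for Computer-Interpretable Clinical Guidelines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for encoding clinical practice guidelines as hierarchical
    computer-interpretable guidelines (CIGs), together with the educational
    machinery built on top of them: a declarative JSON file format with
    structural validation, decision trees with exhaustiveness checking and
    explanation traces, virtual-patient case studies, an automated
    step-by-step simulation engine, a learner verification engine with
    per-category scoring, and the evaluation statistics (percent-correct
    tables, group improvements, Fisher's exact test) used to compare
    guideline-based training against traditional teaching. Ships a
    melanoma-derived demo guideline and case studies, plus a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
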