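Package: mlrkg
Title: Multi-Level Refined Knowledge Graphs from Medical Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds knowledge graphs from plain-text medical articles by
    extracting subject-relation-object triplets from dependency-tagged
    sentences, refining them through staged filters (keyword selection,
    completeness, duplicate elimination, expert-validation annotations),
    and assembling directed multigraphs with relation-frequency sub-graphs,
    joint-entity analysis, interactive HTML export, and keyword-centred
    subgraph distillation. Includes a frequency-based query-triplet
    predictor and ranking metrics (recall, precision, F1, MRR, MAP, nDCG)
    under ground-truth-normalised conventions, plus a seed-reproducible
    synthetic corpus generator with planted ground truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    tibble,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
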