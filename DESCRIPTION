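Package: complexforge
Title: Protein Complex Map Construction from Proteomic Co-Occurrence Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for deriving protein complex maps from high-throughput
    proteomics evidence. Computes hypergeometric co-occurrence (weighted matrix
    model) features from bait-prey presence matrices, builds leak-free
    train/test gold standards from curated complex lists, trains a pluggable
    co-complex interaction classifier, clusters the scored interaction network
    with a two-stage dense-region-growth plus Markov-clustering procedure
    selected by weighted k-clique precision/recall, and interprets the
    resulting complexes via structural mutual-exclusivity calling on paired
    dimer models, lineage-aware co-expression (ALL-IN) scoring, and
    guilt-by-association annotation transfer. Includes a synthetic-data
    generator with planted ground truth so the whole pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    igraph,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
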