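Package: npscreen
Title: Network-Pharmacology Screening of Herbal Compound Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Structure-based activity transfer and target/pathway screening
    for multi-compound herbal libraries. Computes ECFP4 circular fingerprints
    and Tanimoto similarities between literature-annotated active compounds
    and unreported candidates, builds the compound-compound similarity
    network with Cytoscape-compatible exports, aggregates per-compound
    target predictions under average-score and multi-compound-support
    filters, and runs hypergeometric over-representation analysis against
    gene-set collections with cross-source top-k overlap reporting. Includes
    a seeded synthetic-data generator (planted analogs, decoys, targets and
    gene sets) so the whole screening funnel is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ChemmineOB,
    igraph,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
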