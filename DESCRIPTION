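Package: metaboprop
Title: Network Propagation of Metabolomic Enrichment for Candidate Gene
    Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks candidate disease genes for patients with suspected
    metabolic disease by combining untargeted metabolomics with a weighted
    protein functional-linkage network. Per-gene metabolic enrichment seed
    scores are computed from differentially abundant metabolites with a
    one-sided Fisher's exact test, smoothed over the symmetrically
    normalized network by label propagation, and optionally fused with an
    external phenotype score through a neighborhood-aware weighted additive
    model. Includes readers for STRING-style edge lists, gene-metabolite
    annotation tables (TSV or reduced HMDB XML), curated metabolite z-score
    tables and raw LC-MS feature tables, plus a synthetic-fixture generator
    for fully reproducible benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
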