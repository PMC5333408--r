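Package: pathmem
Title: High-Performance In-Memory Pathway Over-Representation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An in-memory engine for pathway over-representation analysis
    (ORA) built from four cooperating data structures: a radix tree
    (Patricia trie) lookup table mapping submitted identifiers to curated
    physical entities, a directed entity graph encoding complex/set
    composition and cross-species ortholog links, a double-linked pathway
    hierarchy tree that aggregates hits recursively into super-pathways,
    and a binomial enrichment test with Benjamini-Hochberg false discovery
    rate control. Knowledge bases are loaded from a plain-text TSV
    interchange format; a seeded generator produces structurally realistic
    synthetic knowledge bases and samples so the whole engine is testable
    without external databases. Results are serialisable under
    content-hash tokens for later server-side filtering, and gene sets can
    be exported in GMT format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
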