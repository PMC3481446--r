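Package: pathconsol
Title: Enrichment and Consolidation of Multi-Source Pathway Collections
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Gene-set pathway enrichment by the one-sided Fisher's exact test,
    together with three complementary algorithms that consolidate redundant
    pathways from merged multi-source pathway databases into representative
    "pathway concepts": iterative Enrichment Consolidation, protein-interaction
    Weighted Consolidation, and experiment-independent de novo consolidation by
    Jaccard distance and hierarchical clustering over gene-membership, GO-Slim
    or interactant attribute sets.  Includes a randomization test for the
    interaction density of consolidated concepts, readers and writers for GMT
    gene-set files, edge lists and gene-to-term maps, a synthetic benchmark
    generator with planted concept structure, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
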