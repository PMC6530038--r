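Package: lahyper
Title: Module-Level Hypergraphs of Dynamic Gene Correlation via Liquid
    Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Scans a gene expression matrix for gene triplets showing
    significant dynamic correlation, quantified by the Liquid Association
    statistic on normal-score transformed data under a low
    pairwise-correlation screen. Significant triplets are selected per
    scouting gene with a permutation null and a kernel-density local
    false discovery rate. Selected triplets are aggregated to the module
    level, with modules defined either from a user gene-set collection
    (GMT) or by clustering genes on their triplet co-involvement
    profiles, yielding a weighted 3-uniform hypergraph whose hyperedge
    weights are fold changes of observed over expected triplet counts.
    Includes synthetic data generators with planted dynamic-correlation
    triplets, sub-hypergraph extraction, and GraphML export of the
    clique expansion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
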