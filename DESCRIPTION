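Package: clanvar
Title: Pairwise Distance Variance Partitioning Along Taxonomic Lineages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for large-scale evolutionary analysis of a protein family
    along a full taxonomic lineage (kingdom to organism). Reads aligned
    amino-acid sequences with per-record taxonomy, computes pairwise
    p-distance matrices under pairwise or complete gap deletion, builds
    neighbor-joining trees with bootstrap clade support, and partitions the
    variance of per-sequence mean p-distances into inter- and intra-clan
    components at every taxonomic bifurcation using unbalanced one-way
    random-effects (model II) ANOVA. Includes a hierarchical
    sequence-evolution simulator with known ground truth (guide tree,
    per-rank substitution rates, optional cross-clan transfer events) so
    every pipeline stage can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    ape,
    phangorn,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
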