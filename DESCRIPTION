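Package: phylofunc
Title: Phylogeny-Function Concordance Analysis for Mixed-Type Trait Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the concordance between the evolutionary history of a
    clade and the functional structure of its species. Builds functional
    dendrograms from mixed-type trait tables (Gower distance, hierarchical
    clustering with method selection by cophenetic correlation), assembles
    matrix-representation-with-parsimony (MRP) supertrees from overlapping
    source trees, and compares phylogenetic and functional trees with four
    statistics: Mantel correlation of distance matrices, relative topological
    difference, branch-length score on normalized trees, and phylogenetic
    signal (Moran's I, Abouheif's Cmean) of a Brownian "functional identity".
    Also computes fair-proportion evolutionary distinctiveness on both trees
    and the correlation between phylogenetic and functional singularity. A
    synthetic-data generator (Yule trees, Brownian traits with tunable signal,
    injectable missingness) exercises every stage without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    cluster,
    vegan,
    picante
Config/testthat/edition: 3
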