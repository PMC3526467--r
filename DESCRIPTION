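Package: cladecarve
Title: Phylogeny-Based Subfamily Delineation for Protein Families
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to divide a large protein family into phylogeny-based
    subfamilies, in the style of the sequence-based subfamily classifications
    used for carbohydrate-active enzyme families such as the glycoside
    hydrolases. The pipeline takes catalytic-module sequences, per-sequence
    metadata and a phylogenetic tree (or an alignment from which a
    neighbor-joining stand-in tree is built), reduces redundancy among
    uncharacterized sequences by greedy centroid clustering at a global
    identity threshold, anchors historical subfamily labels, carves the tree
    into named monophyletic subfamilies under explicit support, size,
    organism-diversity and self-containment rules, and annotates each
    subfamily with its enzyme (EC) specificity, taxonomic distribution and
    catalytic-residue integrity. A sequence-evolution simulator with planted
    subfamily structure makes every stage testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    S4Vectors,
    ape,
    phangorn,
    mclust,
    yaml,
    rlang,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Phylogenetics, Classification, Clustering, Annotation
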