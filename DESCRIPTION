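Package: ibspanel
Title: Identity-by-State Clustering and Informative SNP Panel Selection
    for Cultivar Identification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genotype quality control, identity-by-state (1-IBS) distance
    matrices, Ward hierarchical clustering with outgroup-based tree
    orientation, and reduction of dense SNP sets to compact highly
    informative marker panels ranked by polymorphism information content
    (PIC), with linkage-disequilibrium pruning and Mantel-test fidelity
    checks.  Designed for cultivar identification in clonally propagated
    crops such as date palm, where trees are assigned to known cultivar
    clusters by shared cluster membership.  Includes a seeded synthetic
    genotype generator (Balding-Nichols population structure, clonal
    duplicates, seed progeny, sequencing-depth-driven missingness) so the
    whole pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
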