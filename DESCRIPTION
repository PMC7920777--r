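Package: phyloscape
Title: Spatial Phylogenetics on Gridded Occurrence Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Grid-based spatial phylogenetics for presence-absence
    landscapes: taxon richness, weighted endemism, Faith phylogenetic
    diversity (PD), phylogenetic endemism (PE), and their relative
    variants (RPD, RPE) against an equal-branch-length comparison tree;
    structured (fixed-marginal) randomization tests; categorical
    analysis of neo- and paleo-endemism (CANAPE); and bioregion
    delineation by range-weighted phylo-Sorensen turnover with UPGMA
    clustering. Includes occurrence cleaning and gridding, a synthetic
    landscape generator with planted endemism hotspots and bioregion
    blocks for validation, and a one-command pipeline with a
    reproducibility manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    vegan,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    picante,
    phangorn,
    mclust,
    sp,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
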