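Package: asmbin
Title: Community Assembly Processes via Phylogenetic-Bin-Based Null Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative inference of community assembly processes
    (heterogeneous and homogeneous selection, dispersal limitation,
    homogenizing dispersal, and drift) from taxa abundance tables and a
    phylogeny, by partitioning taxa into phylogenetic bins and analysing
    each bin with phylogenetic (beta net relatedness index) and taxonomic
    (modified Raup-Crick) null models. Includes an entire-community null
    model baseline (QPEN), a neutral-theory benchmark community simulator
    with per-pair ground-truth process importance, concordance-based
    performance evaluation, and distance-matrix statistics (Mantel,
    partial Mantel, multiple regression on distance matrices) linking
    process importance to environmental factors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phytools,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    picante,
    vegan,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
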