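Package: absunifrac
Title: Absolute and Generalized Absolute UniFrac Distances for
    Quantitative Microbiome Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Phylogenetic beta-diversity for absolute-abundance microbiome
    data. Implements weighted UniFrac and generalized UniFrac evaluated on
    absolute (load-scaled) counts alongside their conventional
    relative-abundance forms, unweighted UniFrac, and Bray-Curtis
    dissimilarity; a rarefaction-averaging workflow that subsamples read
    counts to equal depth, rescales by per-sample microbial load, and
    averages distance matrices across iterations; and the evaluation
    statistics used to characterize these metrics (Mantel tests against
    load-difference matrices, one-way PERMANOVA, and sensitivity of the
    distances to noise in load quantification). Includes a fixture
    generator for the four-taxon abundance-grid simulation and randomized
    tree/table/load fixtures, plus a small command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    phyloseq,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
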