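Package: introClust
Title: Introgression Detection with D-Statistics and ABBA-Site Clustering
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects introgression between species from genome-wide SNP data
    and sets of local phylogenetic trees, with explicit safeguards against
    false positives caused by among-species substitution-rate variation.
    Implements Patterson's D-statistic from per-species derived-allele
    frequencies with block-jackknife significance, a positional clustering
    test for strong ABBA sites along chromosomes (one-sample
    Kolmogorov-Smirnov, in a sensitive and a rate-variation-robust version),
    tree-set statistics (constrained Dtree with exact binomial test, and the
    dMRCA statistic on ultrametric local trees), and a four-taxon coalescent
    simulation framework with a timed migration window and branch-rate
    scaling for end-to-end power and false-positive evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    vcfR,
    ape,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: python (>= 3.8) with msprime (>= 1.0) and tskit, for
    the simulation module only
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Genetics, Phylogenetics, PopulationGenetics, SNP
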