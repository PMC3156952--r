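Package: coalsfs
Title: Coalescent Simulation and Joint-SFS Demographic Inference for
    Multi-Population Resequencing Data
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing a resequenced genomic region across many
    populations: genotype-matrix import/export (VCF and TSV), dataset
    construction filters (call rate, monomorphic and multi-allelic site
    removal, combined-Z Hardy-Weinberg screening, outgroup polarization),
    classical diversity statistics (segregating sites, Watterson's theta,
    nucleotide diversity, SNP and haplotype heterozygosity, Tajima's D with
    simulation-based significance), population differentiation
    (Weir-Cockerham FST, Nei's distance, principal-coordinates analysis,
    heterozygosity-distance correlation), a structured-coalescent simulator
    with population splits, exponential growth and migration, and
    Poisson composite-likelihood fitting of multi-population out-of-Africa
    divergence models to the joint site-frequency spectrum, with block
    bootstrap confidence intervals and mutation-rate calibration from
    outgroup divergence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools,
    methods,
    VariantAnnotation,
    SummarizedExperiment,
    GenomeInfoDb,
    BiocGenerics,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
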