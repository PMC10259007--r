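Package: troutherm
Title: Genetic Architecture of Acute Hyperthermia Resistance in Rainbow Trout
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for the genetic architecture of
    acute hyperthermia resistance (time to loss of equilibrium under a
    thermal challenge) in farmed rainbow trout. Provides a factorial-mating
    pedigree and gene-drop genotype simulator, challenge and harvest
    phenotype generators with configurable variance structure, phenotype
    standardisation and quality filters, SNP and individual genotype QC
    with a Hardy-Weinberg test, pedigree (A) and VanRaden genomic (G)
    relationship matrices, AI-REML estimation of variance components,
    heritabilities and genetic correlations under a maternal-effect animal
    model, a BayesC-pi Gibbs sampler for genome-wide association with
    Bayes-factor QTL calling and credibility intervals, genotype contrasts
    at peak SNPs, and isogenic-line concordance checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Rcpp,
    vcfR,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
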