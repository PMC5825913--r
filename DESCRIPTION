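Package: supergs
Title: Mixed-Model GWAS and Genomic Prediction for Multi-Environment Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for inbred crop diversity panels
    phenotyped in multi-environment field trials and genotyped by sequencing.
    Covers two-stage linear mixed-model phenotype adjustment (spatial row/column
    effects, genotype BLUEs, variance components, broad-sense heritability),
    population-genetic structure (VanRaden genomic relationships, kinship
    compression, admixture-model ancestry with cross-validated choice of K,
    linkage-disequilibrium decay under the Hill-Weir drift-equilibrium
    expectation), mixed-model association scans with P3D speed-up and the SUPER
    pseudo-QTN kinship construction, Bonferroni thresholding with flanking-gene
    and pleiotropic-region reporting, and genomic prediction by RR-BLUP/GBLUP,
    Bayesian ridge regression and the Bayesian LASSO with a repeated k-fold
    cross-validation engine and GWAS-p-value-informed marker subsetting.
    A synthetic-data module simulates admixed genotypes with tunable LD decay
    and multi-environment plot-level traits with known heritability so that
    every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    lme4,
    Matrix,
    methods,
    minpack.lm,
    stats,
    utils,
    vcfR,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
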