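Package: gsrice
Title: Genomic Selection with Trait-Specific Markers and Multi-Environment
    Kernel Models for Rice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end genomic selection toolkit for multi-environment
    rice trials: genotype quality control and imputation, linkage
    disequilibrium (LD) based marker pruning, mixed-linear-model GWAS for
    trait- and environment-specific marker selection, single-environment
    kernel prediction (GBLUP and Gaussian-kernel RKHS fitted by EM-REML),
    multi-environment marker-by-environment and Kronecker genetic-covariance
    models fitted by Gibbs sampling, and a CV1/CV2 cross-validation engine
    with Fisher-Z analysis of variance of predictive ability. A synthetic
    data module generates rice-like genotypes (subpopulation structure,
    admixture, tunable LD decay, rare-allele-skewed MAF spectrum) and
    multi-environment field books (augmented and alpha-lattice designs with
    replicated checks) with known ground truth for parameter-recovery
    testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
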