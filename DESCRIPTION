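Package: blockentropy
Title: Entropy-Based Screening of SNPs for Covariate-Sensitive Association
Version: 0.1.0
Authors@R: person("Block Entropy Contributors", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Classifies single-nucleotide polymorphisms (SNPs) whose
    association with a binary outcome is sensitive or insensitive to
    covariates (sex, smoking status, age band, pedigree membership) by
    computing block entropies, block entropy gains and consistency
    entropies over covariate-defined blocks of individuals. Provides
    threshold-based selection rules, a permutation significance framework,
    a synthetic family-cohort simulator for end-to-end testing, readers
    for VCF and dosage-matrix genotype files, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    matrixStats,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr
Config/testthat/edition: 3
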