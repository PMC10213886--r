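Package: aquaimpute
Title: Low-Density SNP Panels, Pedigree-Based Imputation and Genomic
    Prediction for Aquaculture Breeding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate cost-effective genomic selection strategies in
    aquaculture breeding programmes built on full-sib family designs. Simulates
    two-generation populations with realistic family structure and linkage
    disequilibrium, applies standard genotype and sample quality control
    (missingness, exact Hardy-Weinberg test, minor allele frequency, Mendelian
    error rate), designs low-density SNP panels from a high-density map by
    physical spacing, linkage-disequilibrium pruning or random draws, imputes
    offspring genotypes back to high density using their high-density
    genotyped parents, and quantifies both imputation accuracy and
    cross-validated GBLUP prediction accuracy with REML variance components.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
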