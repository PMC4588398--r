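Package: exomeburden
Title: Genome-Wide Rare-Variant Burden and Unique-Variant Gene Association for Case-Control Exomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for rare, protein-changing variants from jointly
    called whole-exome sequencing of a case cohort and two control cohorts.
    Provides per-individual deleteriousness burden scores (summed scaled CADD
    over selected rare variants), cross-cohort batch correction via a
    per-group sequenced-fraction filter with a threshold sweep, Wilcoxon
    rank-sum group comparisons with Bonferroni control, gene-based
    unique-variant association (one-tailed burden and two-tailed C-alpha
    statistics with adaptive permutation empirical p-values, I-values and an
    adjusted Bonferroni correction), clinical cohort-description statistics,
    and a synthetic multi-cohort exome generator with capture-kit missingness
    and configurable planted effects for end-to-end validation.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
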