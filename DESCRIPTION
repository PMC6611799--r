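Package: gradedpool
Title: QTL Mapping from Graded-Pool Sequencing of F2 Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps quantitative trait loci (QTLs) from whole-genome sequencing
    of ordinal graded-pool bulks of an F2 population. F2 individuals are
    ranked by phenotype and pooled into k ordered grades; per-SNP pooled
    allele depths are tested for association with grade by Ridit analysis
    (with Kruskal-Wallis and chi-square comparators), variants are filtered
    in four staged steps, and background noise is reduced by scoring
    non-overlapping 400-kb genomic windows with the fraction of significant
    SNPs, from which candidate intervals are called. Includes an F2
    recombination and pooled-read simulator for power and false-positive
    evaluation under varying coverage, pool size, bulk number and
    misclassification, and a heterosis contribution-rate calculator for
    near-isogenic line comparisons.
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
    vcfR
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
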