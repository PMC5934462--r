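Package: slpburden
Title: Weighted Burden Testing of Rare Variants in Case-Control Exome Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gene-wise and gene-set weighted burden analysis of rare variants
    in case-control exome data. Per-subject scores sum functional weights
    multiplied by allele counts over a gene's rare variants; scores are
    compared between cases and controls with a t test and summarised as a
    signed log10 p (SLP) statistic, separately for singleton, non-singleton
    and combined variant partitions. Includes the accompanying quality-control
    filters (site FILTER status, genotype quality masking, per-cohort
    missingness, heterozygote-deficit exclusion, minor-allele-frequency
    ceiling), ultra-rare-variant (URV) counting with covariate-adjusted
    enrichment regression, an allele-score method for excluding subjects from
    a confounding subpopulation, genotype principal components, QQ and
    Bonferroni reporting helpers, and a seeded synthetic cohort generator
    that emulates the statistical structure these methods assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
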