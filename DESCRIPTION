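Package: autozyg
Title: Homozygosity Mapping and Variant Prioritization in Consanguineous
    Family Sequencing Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for whole-genome sequencing of families with
    recent shared ancestry: trio-based variant filtering under de novo,
    compound-heterozygous, inherited-homozygous, and X-linked recessive
    models; detection of runs of homozygosity (ROH) with per-genome metrics,
    cross-proband merging and parental subtraction; annotation of noncoding
    variants against brain chromatin-state, histone-mark, and predicted
    regulatory element tracks with promoter-enhancer interaction linking;
    rare-variant burden analysis inside versus outside ROHs; and
    multi-criteria candidate-variant prioritization. Ships a synthetic
    consanguineous-cohort generator (pedigrees, gene dropping with
    recombination, planted candidate variants, fixture file bundles) so the
    whole pipeline is testable without protected data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    GenomicRanges,
    IRanges,
    rtracklayer,
    stats,
    tibble,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
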