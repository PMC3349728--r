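Package: cnvburden
Title: Rare Copy-Number-Variant Burden and Association Testing for
    Case-Control Cohorts
Version: 0.1.0
Authors@R:
    person("CNV", "Pipeline Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of copy-number variants (CNVs) in
    case-control cohorts genotyped on SNP arrays: consensus segments from
    two independent callers, copy-number-variable-region (CNVR)
    construction and rare/common classification, one-sided permutation
    burden tests (size, rate, gene count) with quality-stratified
    conditional permutation, CNVR carrier association by two-sided
    Fisher's exact test, sample-size-weighted Stouffer meta-analysis
    across phases, comparative-CT qPCR copy-number estimation with trio
    transmission classification, and deletion-breakpoint arithmetic with
    junction microhomology detection. Includes a synthetic-cohort
    generator emulating two-caller call sets with boundary jitter,
    quality confounding, and planted CNVRs so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
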