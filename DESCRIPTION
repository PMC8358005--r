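Package: recipase
Title: Allelic Imbalance of Expression Analysis for Reciprocal-Cross F1 RNA-Seq
Version: 0.1.0
Authors@R:
    person("Recipase", "Developers", email = "recipase@example.org",
           role = c("aut", "cre"))
Description: Detects allelic imbalance of expression (AIE) and parent-of-origin
    (imprinting-like) effects from reciprocal-cross F1 hybrid RNA-seq allele
    counts. Provides subgroup-level AIE calling by exact binomial tests with
    Benjamini-Hochberg FDR control, differential AIE between reciprocal crosses
    by pooled two-proportion z-tests with allele-fraction-difference thresholds,
    a strong-imprinting screen, Fisher's exact gene-set enrichment with fold
    enrichment statistics, integration of differential-expression tables
    (overlaps and fold-change correlations), N-masking of reference FASTA to
    mitigate mapping bias, SNP-to-gene assignment, and a seeded beta-binomial
    simulator of reciprocal-cross allele counts with planted imprinting and
    cis-regulatory effects so that every inference stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    data.table,
    jsonlite,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
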