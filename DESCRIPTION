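Package: omicdriver
Title: Driver Transcription-Factor Inference from Multi-Omics Concordance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers candidate driver transcription factors from multi-layer
    omics experiments contrasting two conditions. Provides generic differential
    summarization of replicate abundance matrices with layer-specific threshold
    policies, strand-aware promoter-TSS peak annotation and feature-to-gene
    collapsing, regulon (TF target-set) activity scoring with preranked
    weighted Kolmogorov-Smirnov enrichment, consensus-motif scanning with
    motif-proportion enrichment and aggregate Tn5 footprint profiles, and a
    cross-layer z-score concordance integration that selects genes responding
    consistently across omics layers. A synthetic multi-omics study generator
    with planted driver TFs provides ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    jsonlite
Config/testthat/edition: 3
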