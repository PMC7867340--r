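Package: lncforge
Title: Expanding Long Non-Coding RNA Annotation in Vascular Smooth Muscle Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for expanding a reference gene annotation with
    newly assembled transcripts and characterising the resulting long non-coding
    RNA (lncRNA) repertoire in vascular smooth muscle cells (VSMCs). Implements
    reference-transcript filtering, assembled/reference merging with novel-gene
    identifier assignment, a non-redundant cross-dataset union, expression-based
    transcript and gene classification, intron-chain structure validation against
    an independent annotation, CAGE-based transcription start site validation
    with a 5-prime completeness statistic, cell-type enrichment calling from an
    expression atlas, differential-expression thresholding with Fisher's exact
    proportion-enrichment tests and hierarchical clustering, enhancer-transcribed
    lncRNA calling, and pairing of enhancer lncRNAs with candidate co-regulated
    protein-coding targets. Ships a synthetic-data generator with planted ground
    truth so the full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    stats,
    utils,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    BiocGenerics
Config/testthat/edition: 3
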