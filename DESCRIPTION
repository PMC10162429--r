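Package: regulocus
Title: Locus-Centric Integration of Promoter and Enhancer Evidence
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Rule-based derivation of gene promoter boundaries from binned
    sequence-constraint tracks and transcription start site (TSS) evidence,
    CAGE TSS activity quantification (tags per million) with per-cell-type
    summaries, multi-database enhancer corroboration, and chromatin
    interaction based promoter-enhancer linking. Ships a transcribed SCN1A
    evidence catalogue, a synthetic locus simulator with known truth for
    end-to-end recovery testing, and an orchestrating pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3), GenomicRanges
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
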