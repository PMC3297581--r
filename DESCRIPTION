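Package: tfcobind
Title: Integrative ChIP-Seq and RNA-Seq Analysis of Transcription-Factor
    Co-Binding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for establishing co-regulation by two transcription
    factors from ChIP-Seq peak calls and RNA-Seq expression data:
    q-value peak filtering and strand-aware peak-to-gene assignment,
    target-set overlap with hypergeometric significance, nearest-peak
    distance distributions, position-weight-matrix scanning and ZOOPS
    EM de novo motif discovery, RPKM quantification with fractional
    multiread allocation, fold-change differential expression calling,
    and pre-ranked weighted gene-set enrichment analysis. Includes a
    synthetic-data generator that plants known co-binding, motif and
    enrichment structure so every stage can be validated against
    ground truth, and a pipeline driver producing a machine-readable
    report.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
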