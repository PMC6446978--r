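Package: fnrscan
Title: Inference of Oxygen-Responsive (FNR-Type) Regulons from Bacterial
    Time-Series RNA-Seq and Promoter Motif Scanning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to reconstruct the regulon of an oxygen-sensing
    transcription factor of the CRP/FNR family in bacterial genomes.
    Converts gene-level read counts from an anaerobic/microaerobic
    time series to log2 RPKM with per-sample effective-library factors,
    calls putative operons from strand, intergenic distance and
    co-expression, extracts upstream intergenic promoter windows,
    discovers a binding-site motif de novo by ZOOPS
    expectation-maximization, scans promoters on both strands with
    exact position-weight-matrix p-values computed by dynamic
    programming, builds a multi-genome regulon-conservation matrix,
    clusters expression profiles and classifies clusters as positively
    or negatively regulated from the oxygen-phase contrast, and
    cross-validates expression profiles against RT-qPCR copy-number
    series. A synthetic-data module generates genomes with planted
    operons, motifs and phase-structured negative-binomial counts so
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
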