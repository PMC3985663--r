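Package: riftscan
Title: Detection and Characterization of Retrotransposon-Initiated Fusion Transcripts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering and characterizing fusion transcripts
    initiated from the antisense promoter of mouse LINE-1 (L1)
    retrotransposons. Implements calling of retrotransposon-initiated
    fusion transcripts (RIFTs) from exon-array probe intensity matrices
    by per-sample intensity thresholding, consecutive high-probe run
    detection per gene, and proximity/orientation/subfamily/length joins
    to candidate initiating L1 integrants; mapping of transcript 5' ends
    onto L1 element coordinates; splice-donor and translation-start
    scanning; synonymous recoding of coding sequence under A/T-content
    constraints; cross-tissue and cross-strain catalog comparison; and a
    synthetic-data generator that plants fusion transcripts with known
    truth so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
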