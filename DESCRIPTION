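Package: promarch
Title: Promoter Architecture Analysis from Bacterial TSS Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for dissecting sigma-70 promoter architecture from
    genome-scale transcription start site (TSS) maps. Extracts
    strand-aware upstream windows on a no-zero TSS-relative axis,
    discovers -10 and -35 promoter elements with two independent motif
    inference algorithms (a ZOOPS expectation-maximization mixture model
    and an information-content coordinate-ascent aligner), registers
    predicted -10 elements on their conserved TA dinucleotide to classify
    promoters by the base at position -7, computes spacer and
    discriminator length distributions and cross-method agreement, and
    tests -7 base classes for gene essentiality and functional enrichment
    with exact hypergeometric tests. Ships a synthetic-data generator
    with planted ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
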