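Package: leaderless
Title: Detection of -10-Like Promoter Motifs and Leaderless Transcription
    in Bacterial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for locating the hexameric -10-like promoter element
    (consensus TANNNT, most often TACACT in Deinococcus-Thermus genomes)
    immediately upstream of protein-coding genes, and for relating it to
    leaderless transcription. Provides strand-aware upstream window
    extraction from FASTA/GFF3, de novo ZOOPS (zero-or-one occurrence per
    sequence) expectation-maximization motif discovery, PWM log-odds
    scanning with exact p-values from a dynamic-programming score
    distribution, spacer and motif-location statistics, start-codon
    reannotation proposals, classification of per-base transcript-coverage
    step increases downstream of the motif, and a synthetic genome and
    coverage generator with a ground-truth table for benchmarking every
    stage.
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
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
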