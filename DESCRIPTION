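Package: risiRNAkit
Title: Strand-Aware Quantification of Antisense Ribosomal siRNAs and
    ChIP-qPCR Enrichment Arithmetic
Version: 0.1.0
Authors@R:
    person("risiRNAkit", "Developers", email = "risirnakit@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for profiling antisense ribosomal
    small interfering RNAs (risiRNAs) in C. elegans small-RNA sequencing
    libraries: an rDNA transcription-unit coordinate system (5'ETS, 18S,
    ITS1, 5.8S, ITS2, 26S, 3'ETS), a seeded synthetic-library and qPCR
    simulator with truth tables, adapter trimming and an 18-30 nt
    clean-read filter, exact-match strand-aware classification against
    the rDNA unit and decoy transcripts, the bespoke normalization
    number (genome-mapped reads minus sense rRNA and sense mRNA
    fragments), region-proportion, length and 5'-nucleotide profiling
    with bedGraph coverage tracks, and ChIP/RIP-qPCR percent-input,
    fold-change and delta-delta-Ct arithmetic with replicate statistics
    and two-tailed Student's t-tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
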