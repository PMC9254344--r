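Package: uscfseq
Title: Simulation and Fragmentomic Analysis of Ultrashort Single-Stranded
    Cell-Free DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate and analyse the size-partitioned cell-free DNA
    (cfDNA) fragmentome revealed by single-stranded library preparation: a
    deterministic synthetic genome and functional-element fixture generator, a
    fragment simulator producing the bimodal mixture of ultrashort
    single-stranded cfDNA (modal length 50 nt, 25-100 nt) and mononucleosomal
    double-stranded cfDNA (modal length 160 bp with a 10 bp nicked-molecule
    ladder on its left shoulder), in-silico nuclease digestion and library
    preparation operators for strandedness inference, extraction-method
    retention models with lambda spike-in recovery, and the downstream
    statistics: size classification, UMI deduplication, modality and 10 bp
    periodicity estimation, chromosome and binned-coverage profiles with
    Pearson correlation, precedence-resolved functional-element profiles
    (overall and per 10 bp size bin), and electropherogram quantification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
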