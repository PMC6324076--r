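Package: ribotally
Title: Ribosome Profiling Quantification, Offset Calibration and
    Differential Translation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processes transcriptome-aligned ribosome profiling (Ribo-Seq)
    alignments into a per-transcript, per-readlength end-count store and
    derives the downstream analyses that make footprint data interpretable:
    start-codon anchored metagene profiles, per-readlength A-site offset
    calibration by the metagene peak-plus-three rule, readlength and triplet
    periodicity quality control, sub-codon resolution transcript profiles
    with reading-frame decomposition and ORF architecture, multi-sample
    comparison tracks with per-million normalization, and differential
    expression by geometric-mean binned z-scores. A bundled simulator
    generates toy transcriptomes and footprint alignments with known offset
    geometry, periodicity, nested open reading frames and fold changes so
    every analysis is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rsamtools,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
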