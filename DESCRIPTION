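Package: doubletscan
Title: Splicing-Enhancer and G-Quadruplex Profiling of Olduvai-Like Exon Doublets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-nucleotide exonic splicing enhancer/silencer (ESE/ESSseq)
    profiling of exon sequences from hexamer score tables, sliding-window RNA
    G-quadruplex propensity scanning (G4Hunter-style run score, cGcC ratio,
    canonical G4 motif matching), detection of intra-exon tandem duplications
    with mismatch tolerance, and region-versus-background two-sample
    statistics. Includes a seeded generator of synthetic Olduvai-like
    exon-doublet gene architectures (small first exon, purine-rich insertion
    carrying a duplicated block and a pG4-like segment, larger second exon)
    and matched synthetic hexamer score tables, so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    seqinr,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
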