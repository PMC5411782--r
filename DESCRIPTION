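Package: polyqc
Title: Assembly and Annotation Quality Control for Polyploid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quality control and downstream analysis of large
    polyploid genome assemblies and their annotations: k-mer spectra
    copy-number decomposition of read sets against an assembly,
    redundancy-aware scaffold filtering, genetic-map anchoring of scaffolds
    with a seven-class classification scheme, gene-model confidence ranking,
    alternative-splicing event typing with nonsense-mediated-decay
    candidate flagging, homoeolog triad expression analysis for
    allohexaploids, and translocation detection from outlier triads. A
    synthetic allohexaploid genome generator with full ground truth makes
    every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    rlang,
    tibble,
    dplyr,
    tidyr,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ggplot2,
    rtracklayer
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
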