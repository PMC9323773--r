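Package: hervtrace
Title: Discovery and Deep Evolutionary Analysis of Endogenous Retroviruses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mining full-length endogenous retroviruses (ERVs) from
    genome sequences and tracing their deep evolutionary history across a
    time-calibrated species tree. Implements a self-contained local-alignment
    engine (nucleotide and six-frame translated protein search with
    Karlin-Altschul statistics), a reverse-transcriptase-anchored discovery
    pipeline with long-terminal-repeat (LTR) boundary detection and supergroup
    classification, an orthologous-insertion test for vertical transmission
    with graph clustering and MRCA dating, LTR-discordance detection of
    inter-element recombination, strand-aware full-containment intersection
    with ncRNA annotations, and a ground-truth simulator of orthologous
    genomic segments evolving along a species tree. Results are tidy tibbles
    with broom-style accessors and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    ape,
    igraph,
    tibble,
    dplyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    yaml,
    stats,
    utils,
    tools,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
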