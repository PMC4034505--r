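Package: raaindex
Title: Reduced Amino Acid Index Selection and Property-Based Protein
    Sequence Encoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reduces large collections of amino-acid biochemical and
    physical property scales (AAindex-style tables) to a minimal
    informative subset by repeated random-forest permutation importance
    and nested forward selection against an out-of-bag error threshold,
    ships the resulting eight-property reduced index (rAAindex), encodes
    aligned protein sequences as numeric property lattices or as an
    8-bit binary baseline, and characterizes sequence-family diversity
    by principal component analysis of the encoded matrices.  Includes
    seed-deterministic synthetic generators (property tables with
    planted signal, sequence families with property-structured
    divergence) so the whole pipeline is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    ranger,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
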