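Package: maxpars
Title: Maximum-Parsimony Cladistics for Morphological Character Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fitch parsimony analysis of discrete morphological character
    matrices as practised in vertebrate palaeontology: NEXUS and TNT (xread)
    matrix input and output with polymorphic, missing and inapplicable cells;
    Fitch/Hartigan tree-length computation with per-character fit and ensemble
    consistency and retention indices; replicated and hit-driven heuristic
    tree searches with NNI, SPR and TBR branch swapping plus an exhaustive
    oracle for small taxon sets; strict and reduced (rogue-pruned) consensus
    trees; Bremer decay and absolute-frequency bootstrap supports including
    taxon-deletion experiments; ancestral-state and synapomorphy mapping; and
    a seeded simulator of morphological matrices with controllable homoplasy,
    polymorphism and fossil-style missing data for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
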