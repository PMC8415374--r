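Package: ehourglass
Title: Cross-Species Developmental Enhancer Conservation and Positive-Selection Scanning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the evolution of developmental enhancers across
    embryonic stages in two species. Implements stage-specific enhancer calling
    from per-stage accessibility peaks, block-wise cross-species coordinate
    translation, conserved-enhancer calling with Jaccard and Fisher statistics,
    a gapped k-mer linear classifier of chromatin accessibility with per-10-mer
    weights, an in-silico-mutagenesis (deltaSVM) test for positive selection on
    enhancer accessibility with empirical permutation nulls (including
    transition/transversion and dinucleotide-substitution controls), and a
    substitution-versus-polymorphism excess validation. A synthetic two-species,
    five-stage world generator with known ground truth makes the whole pipeline
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    methods,
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    rlang,
    jsonlite,
    yaml,
    withr,
    IRanges,
    S4Vectors,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
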