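Package: smiformer
Title: Target-Conditioned De Novo Molecule Generation with an
    Encoder-Decoder Transformer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates candidate small molecules for a protein target by
    treating de novo design as translation from an amino-acid sequence to a
    SMILES string. Implements character-level tokenization, a from-scratch
    encoder-decoder Transformer (scaled dot-product attention, multi-head
    projection, sinusoidal positional encoding) with an RcppArmadillo
    training engine, beam-search decoding in one-per-target and
    ten-per-target modes, BindingDB-style dataset curation with
    similarity-constrained Monte-Carlo train/test splits based on global
    protein alignment, a molecule evaluation battery (validity, uniqueness,
    reference-set match, physicochemical profiles, drug-likeness compliance,
    nearest-neighbor Tanimoto novelty) backed by RDKit, and rank-based
    enrichment analysis of docking scores (ROC/AUC, Mann-Whitney U and the
    AUC = U/(n1*n2) identity).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    jsonlite,
    ggplot2,
    generics,
    stats,
    utils,
    withr,
    Biostrings
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
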