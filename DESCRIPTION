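Package: charner
Title: Character-Level Clinical Named-Entity Recognition with
    Self-Matching Attention and a Linear-Chain CRF
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Character-level named-entity recognition for clinical
    narrative text. Implements a sequence tagger that combines
    self-matching attention over the input embeddings, two bidirectional
    LSTM passes, and a linear-chain conditional random field with exact
    forward-algorithm training and Viterbi decoding, together with the
    reduced part-of-speech tagging preprocessing that keeps POS tags only
    for general-vocabulary word segments, strict entity-level evaluation
    with boundary/category error taxonomies and length-stratified
    diagnostics, and a synthetic annotated-corpus generator so the whole
    pipeline is testable without access-restricted medical records.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stringr,
    tibble,
    tidyr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
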