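# Shared fixture builders. Everything is generated in code under fixed seeds.

# two-category scheme used by the exhaustive BIO tests
scheme2 <- function() label_scheme(c("Drug", "Operation"))

# small random parameter set for encoder/CRF tests
tiny_params <- function(d = 4L, k = 2L, n = 3L, k_att = k, seed = 1L) {
  withr::with_seed(seed, init_params(d, k, n, k_att))
}

rand_V <- function(m, d, seed = 1L) {
  withr::with_seed(seed, matrix(rnorm(m * d), m, d))
}

# random CRF potentials; transitions fully finite so every path is admissible
rand_potentials <- function(m, n, seed = 1L) {
  withr::with_seed(seed, list(
    em = matrix(rnorm(m * n), m, n),
    trans = matrix(rnorm((n + 2L) * (n + 2L)), n + 2L, n + 2L)
  ))
}

# paper-style preprocessing fixture: a lexicon whose segmenter cuts the
# operation entity into two ordinary-POS pieces
example_lexicon <- function() {
  tibble::tibble(
    word = c("行", "部分小肠", "切除术",
             "直肠癌", "根治术", "头痛",
             "无", "不适"),
    pos = c("v", "n", "v", "n", "n", "n", "d", "n")
  )
}

# small labeled corpus built from explicit sentences
corpus_from_sentences <- function(chars_list, labels_list, pos_list = NULL) {
  purrr::map_dfr(seq_along(chars_list), function(i) {
    out <- tibble::tibble(sentence_id = i, char = chars_list[[i]])
    if (!is.null(pos_list)) out$pos <- pos_list[[i]]
    out$label <- labels_list[[i]]
    out
  })
}
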