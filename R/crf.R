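#' Linear-chain CRF operations
#'
#' A sequence of `m` characters with `n` candidate labels is scored by
#' per-position emission scores `P[i, y_i]` plus label-transition scores
#' `A[y_i, y_{i+1}]`, the sum running from the virtual start state
#' (index `n + 1`) through the labels to the virtual end state (index
#' `n + 2`):
#' `s(y) = sum_{i=0}^{m} A[y_i, y_{i+1}] + sum_{i=1}^{m} P[i, y_i]`.
#' The sequence probability is `exp(s(y))` normalized over all `n^m`
#' label sequences; `crf_log_partition()` computes the log normalizer
#' exactly with the forward algorithm in `O(m n^2)` using per-step
#' log-sum-exp, `crf_nll()` the negative log-likelihood
#' `log Z - s(y)`, and `crf_viterbi()` the maximum-score sequence.
#'
#' Transitions into the start state and out of the end state are
#' conventionally `-Inf`; the functions accept any finite-or-`-Inf`
#' matrix, so fully zero potentials are legal inputs.
#'
#' @param emissions Numeric matrix (m x n) of unnormalized label scores.
#' @param transitions Numeric matrix ((n+2) x (n+2)); rows index the
#'   source label, columns the target.
#' @param y Integer vector of `m` 1-based label indices.
#' @return `crf_score_sequence()`, `crf_log_partition()`, `crf_nll()`:
#'   a single number. `crf_viterbi()`: list with `path` (1-based label
#'   indices) and `score`; ties are broken toward the lowest label index
#'   at every backtracking step, so decoding is deterministic.
#' @name crf
NULL

validate_emissions <- function(emissions) {
  emissions <- as.matrix(emissions)
  if (any(!is.finite(emissions))) {
    abort("`emissions` must be finite.", class = "charner_numeric_error")
  }
  emissions
}

validate_transitions <- function(transitions) {
  transitions <- as.matrix(transitions)
  if (any(is.nan(transitions)) || any(transitions == Inf)) {
    abort("`transitions` must be finite or -Inf.",
          class = "charner_numeric_error")
  }
  transitions
}

#' @rdname crf
#' @export
crf_score_sequence <- function(emissions, transitions, y) {
  emissions <- validate_emissions(emissions)
  transitions <- validate_transitions(transitions)
  if (length(y) != nrow(emissions)) {
    abort("`y` must have one label per emission row.")
  }
  cpp_crf_score(emissions, transitions, as.integer(y) - 1L)
}

#' @rdname crf
#' @export
crf_log_partition <- function(emissions, transitions) {
  emissions <- validate_emissions(emissions)
  transitions <- validate_transitions(transitions)
  lz <- cpp_crf_logZ(emissions, transitions)
  if (is.nan(lz) || lz == Inf) {
    abort("log-partition overflow.", class = "charner_numeric_error")
  }
  lz
}

#' @rdname crf
#' @export
crf_nll <- function(emissions, transitions, y) {
  crf_log_partition(emissions, transitions) -
    crf_score_sequence(emissions, transitions, y)
}

#' @rdname crf
#' @export
crf_viterbi <- function(emissions, transitions) {
  emissions <- validate_emissions(emissions)
  transitions <- validate_transitions(transitions)
  res <- cpp_crf_viterbi(emissions, transitions)
  list(path = as.integer(res$path0) + 1L, score = res$score)
}
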