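#' Initialize encoder and CRF parameters
#'
#' All weight matrices are drawn uniformly from \[-0.1, 0.1\] and biases
#' start at zero; the transition matrix gets the two virtual states
#' appended (start at index `n + 1`, end at `n + 2`) with transitions
#' into start and out of end masked to `-Inf`.
#'
#' @param d Input row width (embedding width, doubled when POS vectors
#'   are concatenated).
#' @param k LSTM hidden size per direction.
#' @param n Number of BIO labels.
#' @param k_att Attention score-space dimension; defaults to `k`.
#' @param vocab_char,vocab_pos Optional vocabulary sizes; when given,
#'   trainable embedding tables `emb_char` (`vocab_char` x `l`) and
#'   `emb_pos` (`vocab_pos` x `l_pos`) are included and `l` must be
#'   supplied.
#' @param l Character embedding width (only with vocabularies).
#' @param l_pos POS embedding width; defaults to `l`.
#' @return Named list of parameter arrays understood by the encoder and
#'   CRF routines: `attn_w`, `attn_Wv`, `attn_Wvh`, `lstm1_fwd`,
#'   `lstm1_bwd`, `lstm2_fwd`, `lstm2_bwd` (each `Wx`, `Wh`, `b`),
#'   `proj_W`, `proj_b`, `trans`, and optionally the embedding tables.
#' @export
init_params <- function(d, k, n, k_att = k, vocab_char = NULL,
                        vocab_pos = NULL, l = NULL, l_pos = l) {
  u <- function(r, c) matrix(runif(r * c, -0.1, 0.1), r, c)
  lstm <- function(input) list(Wx = u(4L * k, input), Wh = u(4L * k, k),
                               b = rep(0, 4L * k))
  trans <- u(n + 2L, n + 2L)
  trans[, n + 1L] <- -Inf   # nothing enters the start state
  trans[n + 2L, ] <- -Inf   # nothing leaves the end state
  params <- list(
    attn_w = runif(k_att, -0.1, 0.1),
    attn_Wv = u(k_att, d), attn_Wvh = u(k_att, d),
    lstm1_fwd = lstm(2L * d), lstm1_bwd = lstm(2L * d),
    lstm2_fwd = lstm(2L * k), lstm2_bwd = lstm(2L * k),
    proj_W = u(2L * k, n), proj_b = rep(0, n),
    trans = trans
  )
  if (!is.null(vocab_char)) {
    stopifnot(!is.null(l))
    params$emb_char <- u(vocab_char, l)
    if (!is.null(vocab_pos)) params$emb_pos <- u(vocab_pos, l_pos)
  }
  params
}

#' Embed a sentence
#'
#' Looks up character (and optionally POS) vectors and concatenates them
#' per position: the input matrix `V` has row width `2l` with POS and `l`
#' without.
#'
#' @param char_ids Integer indices (1-based) into `emb_char`.
#' @param emb_char Character embedding table (vocabulary x `l`).
#' @param pos_ids Optional POS indices, same length as `char_ids`.
#' @param emb_pos POS embedding table (required with `pos_ids`).
#' @return Numeric matrix `V`, one row per character.
#' @export
embed_sentence <- function(char_ids, emb_char, pos_ids = NULL,
                           emb_pos = NULL) {
  if (any(char_ids < 1L) || any(char_ids > nrow(emb_char))) {
    abort("Character index out of embedding-table range.",
          class = "charner_lookup_error")
  }
  V <- emb_char[char_ids, , drop = FALSE]
  if (!is.null(pos_ids)) {
    if (is.null(emb_pos)) abort("`emb_pos` required when `pos_ids` given.")
    if (length(pos_ids) != length(char_ids)) {
      abort("`pos_ids` must match `char_ids` in length.")
    }
    if (any(pos_ids < 1L) || any(pos_ids > nrow(emb_pos))) {
      abort("POS index out of embedding-table range.",
            class = "charner_lookup_error")
    }
    V <- cbind(V, emb_pos[pos_ids, , drop = FALSE])
  }
  unname(V)
}

#' Self-matching attention pooling
#'
#' For every position `t`, scores every position `j` of the same sentence
#' with `s_j^t = w' tanh(Wv v_j + Wvh v_t)`, turns the scores into
#' softmax weights `a^t`, and pools `c_t = sum_i a_i^t v_i`. Weights are
#' non-negative and each row sums to one; for a single-position sentence
#' `c_1 = v_1` whatever the parameters.
#'
#' @param V Input matrix (m x d), one row per character.
#' @param params Parameter list with `attn_w`, `attn_Wv`, `attn_Wvh`
#'   (see [init_params()]).
#' @return List with `context` (m x d, row t is `c_t`) and `weights`
#'   (m x m, row t is `a^t`).
#' @export
attention_pool <- function(V, params) {
  V <- as.matrix(V)
  if (nrow(V) < 1L) abort("`V` must have at least one row.")
  res <- cpp_attention(V, params$attn_w, params$attn_Wv, params$attn_Wvh)
  list(context = res$context, weights = res$weights)
}

#' Self-matching bidirectional encoding
#'
#' Runs the first bidirectional LSTM layer whose input at step `t` is the
#' concatenation `[v_t, c_t]` of the raw input vector and its attention
#' pooling over the whole sentence; the same `c_t` feeds both directions.
#' Output concatenates forward and backward hidden states per position.
#'
#' @inheritParams attention_pool
#' @return Matrix `H` (m x 2k).
#' @export
self_match_encode <- function(V, params) {
  cpp_encode(as.matrix(V), params)$H
}

#' Context encoding layer
#'
#' The second bidirectional LSTM pass over the recoded representation
#' `H`, producing the context features `L` (m x 2k).
#'
#' @param H Matrix from [self_match_encode()].
#' @param params Parameter list with `lstm2_fwd` / `lstm2_bwd`.
#' @return Matrix `L` (m x 2k).
#' @export
context_encode <- function(H, params) {
  H <- as.matrix(H)
  if (ncol(H) != ncol(params$lstm2_fwd$Wx)) {
    abort("`H` width does not match the context-layer input size.")
  }
  fwd <- cpp_lstm_forward(H, params$lstm2_fwd$Wx, params$lstm2_fwd$Wh,
                          params$lstm2_fwd$b)
  rev_idx <- rev(seq_len(nrow(H)))
  bwd <- cpp_lstm_forward(H[rev_idx, , drop = FALSE], params$lstm2_bwd$Wx,
                          params$lstm2_bwd$Wh, params$lstm2_bwd$b)
  cbind(fwd, bwd[rev_idx, , drop = FALSE])
}

#' Project context features to emission scores
#'
#' The linear map `P = L W_p + b_p` producing one unnormalized score per
#' label and position — the emission matrix the CRF consumes.
#'
#' @param L Context feature matrix (m x 2k).
#' @param W Projection weights (2k x n).
#' @param b Bias vector of length n.
#' @return Emission matrix (m x n).
#' @export
project_emissions <- function(L, W, b) {
  L <- as.matrix(L); W <- as.matrix(W)
  if (ncol(L) != nrow(W) || length(b) != ncol(W)) {
    abort("Shape mismatch in emission projection.")
  }
  sweep(L %*% W, 2L, b, "+")
}

#' Full encoder pass for one sentence
#'
#' Attention pooling, both bidirectional LSTM layers, and the emission
#' projection in one call (single C++ pass).
#'
#' @inheritParams attention_pool
#' @return List with `context`, `weights`, `H`, `L`, and `emissions`.
#' @export
encode_sentence <- function(V, params) {
  V <- as.matrix(V)
  if (nrow(V) < 1L) abort("`V` must have at least one row.")
  res <- cpp_encode(V, params)
  res[c("context", "weights", "H", "L", "emissions")]
}

# ---- Adam ------------------------------------------------------------------

# recursive elementwise walk over nested parameter lists
walk_params <- function(p, g, f) {
  if (is.list(p)) {
    out <- Map(function(pp, gg) walk_params(pp, gg, f), p, g[names(p)])
    return(out)
  }
  f(p, g)
}

adam_init <- function(params) {
  zero <- function(p, g) p * 0
  list(m = walk_params(params, params, zero),
       v = walk_params(params, params, zero),
       t = 0L)
}

# One Adam update. Masked (-Inf) transition entries have zero gradients by
# construction, zero moments, and therefore stay -Inf (x - 0 = x).
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- walk3(params, grads, state$m,
                   function(p, g, s) beta1 * s + (1 - beta1) * g)
  state$v <- walk3(params, grads, state$v,
                   function(p, g, s) beta2 * s + (1 - beta2) * g * g)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  params <- walk3(params, state$m, state$v, function(p, m, v) {
    mask <- is.finite(p)
    step <- lr * (m / c1) / (sqrt(v / c2) + eps)
    p[mask] <- p[mask] - step[mask]
    p
  })
  list(params = params, state = state)
}

walk3 <- function(a, b, d, f) {
  if (is.list(a)) return(Map(function(x, y, z) walk3(x, y, z, f),
                             a, b[names(a)], d[names(a)]))
  f(a, b, d)
}
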