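# Independent reference implementations used as oracles. All of these are
# deliberately naive (scalar loops, exhaustive enumeration) and share no code
# with the package internals they check.

r_sigmoid <- function(x) 1 / (1 + exp(-x))

# attention by scalar loops over positions
r_attention <- function(V, w, Wv, Wvh) {
  m <- nrow(V)
  S <- matrix(0, m, m)
  for (t in seq_len(m)) {
    for (j in seq_len(m)) {
      S[t, j] <- sum(w * tanh(Wv %*% V[j, ] + Wvh %*% V[t, ]))
    }
  }
  A <- matrix(0, m, m)
  C <- matrix(0, m, ncol(V))
  for (t in seq_len(m)) {
    e <- exp(S[t, ] - max(S[t, ]))
    A[t, ] <- e / sum(e)
    for (i in seq_len(m)) C[t, ] <- C[t, ] + A[t, i] * V[i, ]
  }
  list(weights = A, context = C)
}

# one LSTM direction, step by step (gates i, f, g, o; zero initial state)
r_lstm <- function(X, Wx, Wh, b) {
  m <- nrow(X)
  k <- ncol(Wh)
  H <- matrix(0, m, k)
  h <- rep(0, k); cc <- rep(0, k)
  for (t in seq_len(m)) {
    z <- as.vector(Wx %*% X[t, ] + Wh %*% h + b)
    i <- r_sigmoid(z[1:k])
    f <- r_sigmoid(z[(k + 1):(2 * k)])
    g <- tanh(z[(2 * k + 1):(3 * k)])
    o <- r_sigmoid(z[(3 * k + 1):(4 * k)])
    cc <- f * cc + i * g
    h <- o * tanh(cc)
    H[t, ] <- h
  }
  H
}

r_bilstm <- function(X, fwd, bwd) {
  m <- nrow(X)
  Hf <- r_lstm(X, fwd$Wx, fwd$Wh, fwd$b)
  Hb <- r_lstm(X[rev(seq_len(m)), , drop = FALSE], bwd$Wx, bwd$Wh, bwd$b)
  cbind(Hf, Hb[rev(seq_len(m)), , drop = FALSE])
}

# full encoder by composition of the naive pieces
r_encode <- function(V, p) {
  att <- r_attention(V, p$attn_w, p$attn_Wv, p$attn_Wvh)
  X1 <- cbind(V, att$context)
  H <- r_bilstm(X1, p$lstm1_fwd, p$lstm1_bwd)
  L <- r_bilstm(H, p$lstm2_fwd, p$lstm2_bwd)
  em <- L %*% p$proj_W
  for (t in seq_len(nrow(em))) em[t, ] <- em[t, ] + p$proj_b
  list(H = H, L = L, emissions = em, context = att$context,
       weights = att$weights)
}

# exhaustive CRF quantities over all n^m tag sequences (1-based paths)
r_crf_enumerate <- function(em, trans) {
  m <- nrow(em); n <- ncol(em)
  start <- n + 1L; end <- n + 2L
  grid <- as.matrix(expand.grid(rep(list(seq_len(n)), m)))
  scores <- apply(grid, 1L, function(y) {
    s <- trans[start, y[1]] + em[1, y[1]]
    if (m > 1) for (t in 2:m) s <- s + trans[y[t - 1], y[t]] + em[t, y[t]]
    s + trans[y[m], end]
  })
  mx <- max(scores)
  logZ <- mx + log(sum(exp(scores - mx)))
  best <- which.max(scores)
  list(logZ = logZ, max_score = max(scores), scores = scores,
       sequences = grid, best = grid[best, ])
}

# strict matching by nested loops (no joins)
r_strict_counts <- function(gold, pred) {
  tp <- 0L
  used <- rep(FALSE, nrow(gold))
  if (nrow(pred) > 0) {
    for (i in seq_len(nrow(pred))) {
      for (j in seq_len(nrow(gold))) {
        if (!used[j] &&
            pred$sentence_id[i] == gold$sentence_id[j] &&
            pred$category[i] == gold$category[j] &&
            pred$start[i] == gold$start[j] &&
            pred$end[i] == gold$end[j]) {
          tp <- tp + 1L
          used[j] <- TRUE
          break
        }
      }
    }
  }
  p <- if (nrow(pred) > 0) tp / nrow(pred) else 0
  r <- if (nrow(gold) > 0) tp / nrow(gold) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(tp = tp, fp = nrow(pred) - tp, fn = nrow(gold) - tp,
       precision = p, recall = r, f1 = f)
}

# taxonomy by nested loops, mirroring the documented tie-break
r_taxonomy <- function(gold, pred) {
  out <- c(boundary_correct_category_wrong = 0L,
           boundary_wrong_category_correct = 0L,
           boundary_wrong_category_wrong = 0L,
           spurious = 0L)
  for (i in seq_len(nrow(pred))) {
    exact <- any(gold$sentence_id == pred$sentence_id[i] &
                   gold$category == pred$category[i] &
                   gold$start == pred$start[i] & gold$end == pred$end[i])
    if (exact) next
    g <- gold[gold$sentence_id == pred$sentence_id[i], , drop = FALSE]
    if (nrow(g) > 0) {
      ov <- pmin(g$end, pred$end[i]) - pmax(g$start, pred$start[i])
      g <- g[ov > 0, , drop = FALSE]; ov <- ov[ov > 0]
    }
    if (nrow(g) == 0) { out["spurious"] <- out["spurious"] + 1L; next }
    best <- order(-ov, g$start, -(g$end - g$start))[1]
    b_ok <- g$start[best] == pred$start[i] && g$end[best] == pred$end[i]
    c_ok <- g$category[best] == pred$category[i]
    key <- if (b_ok && !c_ok) "boundary_correct_category_wrong"
    else if (!b_ok && c_ok) "boundary_wrong_category_correct"
    else "boundary_wrong_category_wrong"
    out[key] <- out[key] + 1L
  }
  out
}

# length histogram by plain loops
r_length_hist <- function(gold, pred) {
  bins <- c("1-5", "6-10", "11-15", ">15")
  gold_n <- setNames(rep(0L, 4L), bins)
  correct <- setNames(rep(0L, 4L), bins)
  bin_of <- function(len) if (len <= 5) 1L else if (len <= 10) 2L
  else if (len <= 15) 3L else 4L
  for (j in seq_len(nrow(gold))) {
    b <- bin_of(gold$end[j] - gold$start[j])
    gold_n[b] <- gold_n[b] + 1L
    hit <- any(pred$sentence_id == gold$sentence_id[j] &
                 pred$category == gold$category[j] &
                 pred$start == gold$start[j] & pred$end == gold$end[j])
    if (hit) correct[b] <- correct[b] + 1L
  }
  list(gold = gold_n, correct = correct)
}
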