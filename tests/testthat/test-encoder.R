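test_that("embedding lookup concatenates character and POS vectors", {
  emb_c <- diag(3)           # one-hot toy tables
  emb_p <- 2 * diag(3)
  V <- embed_sentence(c(2L, 1L), emb_c, c(3L, 3L), emb_p)
  expect_equal(dim(V), c(2L, 6L))
  expect_equal(V[1, ], c(0, 1, 0, 0, 0, 2))
  expect_equal(V[2, ], c(1, 0, 0, 0, 0, 2))

  # ablation mode: without POS the input is the character table rows
  expect_equal(embed_sentence(c(2L, 1L), emb_c), emb_c[c(2, 1), ])

  # single-character sentence keeps matrix shape
  expect_equal(dim(embed_sentence(1L, emb_c, 1L, emb_p)), c(1L, 6L))

  expect_error(embed_sentence(4L, emb_c), class = "charner_lookup_error")
  expect_error(embed_sentence(1L, emb_c, 9L, emb_p),
               class = "charner_lookup_error")
})

test_that("attention weights form a distribution and degenerate cases are exact", {
  p <- tiny_params(d = 3, k = 2, seed = 21)
  # m=1: the softmax over a singleton makes c_1 = v_1 for any parameters
  v <- matrix(c(0.3, -2, 5), 1, 3)
  att <- attention_pool(v, p)
  expect_equal(att$weights, matrix(1, 1, 1))
  expect_equal(att$context, v)

  # identical rows give uniform weights by symmetry
  V <- matrix(rep(c(1, 2, 3), each = 4), 4, 3)
  att2 <- attention_pool(V, p)
  expect_equal(att2$weights, matrix(0.25, 4, 4))

  # distribution property under random parameters and inputs
  for (s in 1:25) {
    m <- sample(1:7, 1)
    pp <- tiny_params(d = 3, k = 2, seed = 300 + s)
    Vr <- rand_V(m, 3, seed = 300 + s)
    w <- attention_pool(Vr, pp)$weights
    expect_true(all(w >= 0))
    expect_equal(rowSums(w), rep(1, m), tolerance = 1e-6)
  }
})

test_that("attention matches a step-by-step scalar computation", {
  # small integer parameters, m=3, d=2, k=2
  w <- c(1, -1)
  Wv <- matrix(c(1, 0, -1, 2), 2, 2)
  Wvh <- matrix(c(0, 1, 1, -1), 2, 2)
  V <- matrix(c(1, 0, -1, 0, 2, 1), 3, 2)
  p <- list(attn_w = w, attn_Wv = Wv, attn_Wvh = Wvh)
  got <- attention_pool(V, p)
  ref <- r_attention(V, w, Wv, Wvh)
  expect_equal(got$weights, ref$weights, tolerance = 1e-12)
  expect_equal(got$context, ref$context, tolerance = 1e-12)
})

test_that("attention pooling is invariant to permuting the other positions", {
  p <- tiny_params(d = 3, k = 2, seed = 33)
  V <- rand_V(5, 3, seed = 33)
  c1 <- attention_pool(V, p)$context[1, ]
  perm <- c(1, 4, 2, 5, 3)  # keeps position 1 fixed
  c1p <- attention_pool(V[perm, ], p)$context[1, ]
  expect_equal(c1, c1p, tolerance = 1e-12)
})

test_that("the self-matching layer agrees with a naive per-step loop", {
  p <- tiny_params(d = 3, k = 2, seed = 41)
  V <- rand_V(4, 3, seed = 41)
  ref <- r_encode(V, p)
  expect_equal(self_match_encode(V, p), ref$H, tolerance = 1e-12)

  # m=1: both directions see [v_1, c_1] = [v_1, v_1]
  v1 <- rand_V(1, 3, seed = 42)
  H1 <- self_match_encode(v1, p)
  x1 <- cbind(v1, v1)
  expect_equal(H1, cbind(r_lstm(x1, p$lstm1_fwd$Wx, p$lstm1_fwd$Wh,
                                p$lstm1_fwd$b),
                         r_lstm(x1, p$lstm1_bwd$Wx, p$lstm1_bwd$Wh,
                                p$lstm1_bwd$b)),
               tolerance = 1e-12)
})

test_that("zero inputs with zero parameters stay at the zero fixed point", {
  p <- tiny_params(d = 2, k = 2, n = 3, seed = 1)
  zero <- function(x) x * 0
  p$attn_w <- zero(p$attn_w); p$attn_Wv <- zero(p$attn_Wv)
  p$attn_Wvh <- zero(p$attn_Wvh)
  for (nm in c("lstm1_fwd", "lstm1_bwd", "lstm2_fwd", "lstm2_bwd")) {
    p[[nm]] <- lapply(p[[nm]], zero)
  }
  V0 <- matrix(0, 3, 2)
  expect_equal(self_match_encode(V0, p), matrix(0, 3, 4))
  expect_equal(context_encode(matrix(0, 3, 4), p), matrix(0, 3, 4))
})

test_that("the context layer agrees with a naive loop and checks shapes", {
  p <- tiny_params(d = 3, k = 2, seed = 55)
  H <- rand_V(5, 4, seed = 55)  # 2k = 4
  ref <- r_bilstm(H, p$lstm2_fwd, p$lstm2_bwd)
  expect_equal(context_encode(H, p), ref, tolerance = 1e-12)
  expect_equal(dim(context_encode(rand_V(1, 4, seed = 56), p)), c(1L, 4L))
  expect_error(context_encode(rand_V(2, 3, seed = 57), p), "width")
})

test_that("emission projection is an exact affine map", {
  W <- matrix(c(1, 2, 0, -1, 3, 1, 2, 0), 4, 2)
  b <- c(0.5, -0.5)
  expect_equal(project_emissions(matrix(0, 3, 4), W, b),
               matrix(rep(b, each = 3), 3, 2))
  # n=1 degenerate label set
  expect_equal(dim(project_emissions(matrix(1, 5, 4), W[, 1, drop = FALSE],
                                     0)), c(5L, 1L))
  # random case vs an explicit double loop
  L <- rand_V(3, 4, seed = 61)
  ref <- matrix(0, 3, 2)
  for (i in 1:3) for (j in 1:2) ref[i, j] <- sum(L[i, ] * W[, j]) + b[j]
  expect_equal(project_emissions(L, W, b), ref, tolerance = 1e-12)
  expect_error(project_emissions(L, W[1:3, ], b), "Shape")
})

test_that("the full encoder is deterministic and equals the naive composition", {
  p <- tiny_params(d = 4, k = 3, n = 5, seed = 71)
  V <- rand_V(6, 4, seed = 71)
  enc1 <- encode_sentence(V, p)
  enc2 <- encode_sentence(V, p)
  expect_identical(enc1, enc2)
  ref <- r_encode(V, p)
  expect_equal(enc1$emissions, ref$emissions, tolerance = 1e-10)
  expect_equal(enc1$L, ref$L, tolerance = 1e-10)
  expect_equal(enc1$context, ref$context, tolerance = 1e-10)
})

test_that("analytic gradients match finite differences on a tiny model", {
  p <- tiny_params(d = 4, k = 2, n = 3, seed = 81)
  V <- rand_V(3, 4, seed = 81)
  y0 <- c(0L, 2L, 1L)
  res <- charner:::cpp_sentence_loss_grad(V, y0, p)
  eps <- 1e-5
  get_leaf <- function(pp, path) if (length(path) == 1) pp[[path]]
  else pp[[path[1]]][[path[2]]]
  set_leaf <- function(pp, path, v) {
    if (length(path) == 1) pp[[path]][] <- v
    else pp[[path[1]]][[path[2]]][] <- v
    pp
  }
  layer_paths <- expand.grid(
    layer = c("lstm1_fwd", "lstm1_bwd", "lstm2_fwd", "lstm2_bwd"),
    w = c("Wx", "Wh", "b"), stringsAsFactors = FALSE
  )
  paths <- c(list("attn_w", "attn_Wv", "attn_Wvh", "proj_W", "proj_b",
                  "trans"),
             purrr::map(seq_len(nrow(layer_paths)),
                        ~ c(layer_paths$layer[.x], layer_paths$w[.x])))
  worst <- 0
  for (path in paths) {
    theta <- get_leaf(p, path)
    g_ana <- as.vector(get_leaf(res$grads, path))
    idx <- which(is.finite(theta))
    # probe a subset of coordinates per block to keep the test quick
    idx <- idx[seq(1L, length(idx), length.out = min(10L, length(idx)))]
    for (i in idx) {
      v <- theta; v[i] <- v[i] + eps
      lp <- charner:::cpp_sentence_loss(V, y0, set_leaf(p, path, v))
      v <- theta; v[i] <- v[i] - eps
      lm <- charner:::cpp_sentence_loss(V, y0, set_leaf(p, path, v))
      num <- (lp - lm) / (2 * eps)
      worst <- max(worst, abs(num - g_ana[i]) / max(1, abs(num)))
    }
  }
  expect_lt(worst, 1e-6)
})

test_that("batched gradient accumulation equals the sum of per-sentence passes", {
  p <- tiny_params(d = 3, k = 2, n = 3, seed = 91)
  withr::with_seed(91, {
    p$emb_char <- matrix(runif(5 * 2, -0.1, 0.1), 5, 2)
    p$emb_pos <- matrix(runif(3 * 1, -0.1, 0.1), 3, 1)
  })
  chars <- list(c(0L, 2L, 4L), c(1L, 3L))
  pos <- list(c(0L, 1L, 2L), c(2L, 0L))
  ys <- list(c(0L, 1L, 2L), c(2L, 0L))
  batch <- charner:::cpp_batch_loss_grad(chars, pos, ys, p)
  singles <- lapply(1:2, function(i) {
    charner:::cpp_batch_loss_grad(chars[i], pos[i], ys[i], p)
  })
  expect_equal(batch$loss_sum, singles[[1]]$loss_sum + singles[[2]]$loss_sum)
  add <- function(a, b) if (is.list(a)) Map(add, a, b[names(a)]) else a + b
  expect_equal(batch$grads[sort(names(batch$grads))],
               add(singles[[1]]$grads,
                   singles[[2]]$grads)[sort(names(batch$grads))],
               tolerance = 1e-12)
})
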