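// Numeric core: self-matching attention, stacked bidirectional LSTMs,
// linear emission projection, and a linear-chain CRF (forward algorithm,
// Viterbi, analytic gradients). Everything is double precision and
// deterministic; all stochastic behaviour lives on the R side.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::rowvec;
using arma::cube;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// log-sum-exp that tolerates -Inf entries (all -Inf -> -Inf)
static inline double lse(const vec& x) {
  double m = x.max();
  if (!std::isfinite(m)) return m;
  return m + std::log(arma::accu(arma::exp(x - m)));
}

static inline vec sigmoid(const vec& x) {
  return 1.0 / (1.0 + arma::exp(-x));
}

// ---------------------------------------------------------------------------
// LSTM (standard cell, gates i,f,g,o; zero initial state, no peepholes)
// ---------------------------------------------------------------------------

struct LstmWeights {
  mat Wx;  // 4k x in
  mat Wh;  // 4k x k
  vec b;   // 4k
};

struct LstmCache {
  mat gi, gf, gg, go, c, tc, h;  // each m x k
};

static LstmWeights get_lstm(const List& l) {
  return LstmWeights{as<mat>(l["Wx"]), as<mat>(l["Wh"]), as<vec>(l["b"])};
}

static mat lstm_forward(const mat& X, const LstmWeights& w, LstmCache& ca) {
  const int m = X.n_rows;
  const int k = w.Wh.n_cols;
  ca.gi.set_size(m, k); ca.gf.set_size(m, k); ca.gg.set_size(m, k);
  ca.go.set_size(m, k); ca.c.set_size(m, k); ca.tc.set_size(m, k);
  ca.h.set_size(m, k);
  mat Zx = X * w.Wx.t();  // m x 4k
  vec h(k, arma::fill::zeros), c(k, arma::fill::zeros);
  for (int t = 0; t < m; ++t) {
    vec z = Zx.row(t).t() + w.Wh * h + w.b;
    vec i = sigmoid(z.subvec(0, k - 1));
    vec f = sigmoid(z.subvec(k, 2 * k - 1));
    vec g = arma::tanh(z.subvec(2 * k, 3 * k - 1));
    vec o = sigmoid(z.subvec(3 * k, 4 * k - 1));
    c = f % c + i % g;
    vec tc = arma::tanh(c);
    h = o % tc;
    ca.gi.row(t) = i.t(); ca.gf.row(t) = f.t(); ca.gg.row(t) = g.t();
    ca.go.row(t) = o.t(); ca.c.row(t) = c.t(); ca.tc.row(t) = tc.t();
    ca.h.row(t) = h.t();
  }
  return ca.h;
}

struct LstmGrads {
  mat Wx, Wh;
  vec b;
  void init(const LstmWeights& w) {
    Wx.zeros(w.Wx.n_rows, w.Wx.n_cols);
    Wh.zeros(w.Wh.n_rows, w.Wh.n_cols);
    b.zeros(w.b.n_elem);
  }
};

static void lstm_backward(const mat& X, const LstmWeights& w,
                          const LstmCache& ca, const mat& dH,
                          mat& dX, LstmGrads& g) {
  const int m = X.n_rows;
  const int k = w.Wh.n_cols;
  vec dh_next(k, arma::fill::zeros), dc_next(k, arma::fill::zeros);
  for (int t = m - 1; t >= 0; --t) {
    vec dh = dH.row(t).t() + dh_next;
    vec gi = ca.gi.row(t).t(), gf = ca.gf.row(t).t();
    vec gg = ca.gg.row(t).t(), go = ca.go.row(t).t();
    vec tc = ca.tc.row(t).t();
    vec dgo = dh % tc;
    vec dc = dc_next + dh % go % (1.0 - tc % tc);
    vec c_prev = (t > 0) ? vec(ca.c.row(t - 1).t())
                         : vec(k, arma::fill::zeros);
    vec h_prev = (t > 0) ? vec(ca.h.row(t - 1).t())
                         : vec(k, arma::fill::zeros);
    vec dgi = dc % gg, dgg = dc % gi, dgf = dc % c_prev;
    dc_next = dc % gf;
    vec dz = arma::join_cols(dgi % gi % (1.0 - gi),
                             dgf % gf % (1.0 - gf),
                             dgg % (1.0 - gg % gg),
                             dgo % go % (1.0 - go));
    g.Wx += dz * X.row(t);
    g.Wh += dz * h_prev.t();
    g.b += dz;
    dX.row(t) += (w.Wx.t() * dz).t();
    dh_next = w.Wh.t() * dz;
  }
}

// ---------------------------------------------------------------------------
// Self-matching attention over the raw input rows
// scores s_j^t = w' tanh(Wv v_j + Wvh v_t); a^t = softmax_j; c_t = sum a_i v_i
// ---------------------------------------------------------------------------

static void attention_forward(const mat& V, const vec& w, const mat& Wv,
                              const mat& Wvh, mat& A, mat& C, cube& T) {
  const int m = V.n_rows;
  const int ka = w.n_elem;
  mat U = Wv * V.t();    // ka x m  (per-j term)
  mat Q = Wvh * V.t();   // ka x m  (per-t term)
  T.set_size(ka, m, m);  // T.slice(t).col(j) = tanh(U_j + Q_t)
  mat S(m, m);
  for (int t = 0; t < m; ++t) {
    for (int j = 0; j < m; ++j) {
      vec tj = arma::tanh(U.col(j) + Q.col(t));
      T.slice(t).col(j) = tj;
      S(t, j) = arma::dot(w, tj);
    }
  }
  A.set_size(m, m);
  for (int t = 0; t < m; ++t) {
    rowvec s = S.row(t);
    double mx = s.max();
    rowvec e = arma::exp(s - mx);
    A.row(t) = e / arma::accu(e);
  }
  C = A * V;
}

static void attention_backward(const mat& V, const mat& A, const cube& T,
                               const vec& w, const mat& Wv, const mat& Wvh,
                               const mat& dC, mat& dV, vec& dw, mat& dWv,
                               mat& dWvh) {
  const int m = V.n_rows;
  const int ka = w.n_elem;
  mat dA = dC * V.t();  // m x m
  dV += A.t() * dC;
  mat dU(ka, m, arma::fill::zeros), dQ(ka, m, arma::fill::zeros);
  for (int t = 0; t < m; ++t) {
    double rd = arma::dot(A.row(t), dA.row(t));
    for (int j = 0; j < m; ++j) {
      double ds = A(t, j) * (dA(t, j) - rd);  // softmax jacobian
      if (ds == 0.0) continue;
      vec tj = T.slice(t).col(j);
      dw += ds * tj;
      vec dT = ds * (w % (1.0 - tj % tj));
      dU.col(j) += dT;
      dQ.col(t) += dT;
    }
  }
  dWv += dU * V;
  dWvh += dQ * V;
  dV += (Wv.t() * dU).t();
  dV += (Wvh.t() * dQ).t();
}

// ---------------------------------------------------------------------------
// Encoder = attention + two bidirectional LSTM layers + linear projection
// ---------------------------------------------------------------------------

struct EncParams {
  vec attn_w;
  mat attn_Wv, attn_Wvh;
  LstmWeights l1f, l1b, l2f, l2b;
  mat proj_W;
  vec proj_b;
  mat trans;
};

static EncParams get_params(const List& p) {
  EncParams out;
  out.attn_w = as<vec>(p["attn_w"]);
  out.attn_Wv = as<mat>(p["attn_Wv"]);
  out.attn_Wvh = as<mat>(p["attn_Wvh"]);
  out.l1f = get_lstm(p["lstm1_fwd"]);
  out.l1b = get_lstm(p["lstm1_bwd"]);
  out.l2f = get_lstm(p["lstm2_fwd"]);
  out.l2b = get_lstm(p["lstm2_bwd"]);
  out.proj_W = as<mat>(p["proj_W"]);
  out.proj_b = as<vec>(p["proj_b"]);
  if (p.containsElementNamed("trans")) out.trans = as<mat>(p["trans"]);
  return out;
}

struct EncGrads {
  vec attn_w;
  mat attn_Wv, attn_Wvh;
  LstmGrads l1f, l1b, l2f, l2b;
  mat proj_W;
  vec proj_b;
  mat trans;
  void init(const EncParams& p) {
    attn_w.zeros(p.attn_w.n_elem);
    attn_Wv.zeros(p.attn_Wv.n_rows, p.attn_Wv.n_cols);
    attn_Wvh.zeros(p.attn_Wvh.n_rows, p.attn_Wvh.n_cols);
    l1f.init(p.l1f); l1b.init(p.l1b); l2f.init(p.l2f); l2b.init(p.l2b);
    proj_W.zeros(p.proj_W.n_rows, p.proj_W.n_cols);
    proj_b.zeros(p.proj_b.n_elem);
    if (p.trans.n_elem > 0) trans.zeros(p.trans.n_rows, p.trans.n_cols);
  }
};

struct EncCache {
  mat A, C, X1, X1r, H, Hr, L;
  cube T;
  LstmCache c1f, c1b, c2f, c2b;
};

static mat encoder_forward(const mat& V, const EncParams& P, EncCache& ca) {
  attention_forward(V, P.attn_w, P.attn_Wv, P.attn_Wvh, ca.A, ca.C, ca.T);
  ca.X1 = arma::join_rows(V, ca.C);
  mat H1f = lstm_forward(ca.X1, P.l1f, ca.c1f);
  ca.X1r = arma::flipud(ca.X1);
  mat H1br = lstm_forward(ca.X1r, P.l1b, ca.c1b);
  ca.H = arma::join_rows(H1f, arma::flipud(H1br));
  mat H2f = lstm_forward(ca.H, P.l2f, ca.c2f);
  ca.Hr = arma::flipud(ca.H);
  mat H2br = lstm_forward(ca.Hr, P.l2b, ca.c2b);
  ca.L = arma::join_rows(H2f, arma::flipud(H2br));
  return ca.L * P.proj_W + arma::repmat(P.proj_b.t(), V.n_rows, 1);
}

static mat encoder_backward(const mat& V, const EncParams& P,
                            const EncCache& ca, const mat& d_em,
                            EncGrads& G) {
  const int m = V.n_rows;
  const int d = V.n_cols;
  const int k = P.l1f.Wh.n_cols;
  G.proj_W += ca.L.t() * d_em;
  G.proj_b += arma::sum(d_em, 0).t();
  mat dL = d_em * P.proj_W.t();  // m x 2k
  mat dH(m, 2 * k, arma::fill::zeros);
  lstm_backward(ca.H, P.l2f, ca.c2f, dL.cols(0, k - 1), dH, G.l2f);
  mat dHr(m, 2 * k, arma::fill::zeros);
  lstm_backward(ca.Hr, P.l2b, ca.c2b,
                arma::flipud(dL.cols(k, 2 * k - 1)), dHr, G.l2b);
  dH += arma::flipud(dHr);
  mat dX1(m, ca.X1.n_cols, arma::fill::zeros);
  lstm_backward(ca.X1, P.l1f, ca.c1f, dH.cols(0, k - 1), dX1, G.l1f);
  mat dX1r(m, ca.X1.n_cols, arma::fill::zeros);
  lstm_backward(ca.X1r, P.l1b, ca.c1b,
                arma::flipud(dH.cols(k, 2 * k - 1)), dX1r, G.l1b);
  dX1 += arma::flipud(dX1r);
  mat dV = dX1.cols(0, d - 1);
  mat dCmat = dX1.cols(d, 2 * d - 1);
  attention_backward(V, ca.A, ca.T, P.attn_w, P.attn_Wv, P.attn_Wvh, dCmat,
                     dV, G.attn_w, G.attn_Wv, G.attn_Wvh);
  return dV;
}

// ---------------------------------------------------------------------------
// Linear-chain CRF with virtual start (index n) and end (index n+1) states
// transitions: (n+2) x (n+2); emissions: m x n
// ---------------------------------------------------------------------------

static void check_pot(const mat& em, const mat& trans) {
  const int n = em.n_cols;
  if (em.n_rows < 1) stop("emissions must have m >= 1 rows");
  if ((int)trans.n_rows != n + 2 || (int)trans.n_cols != n + 2)
    stop("`transitions` must be (n+2) x (n+2) with n = ncol(emissions)");
  if (em.has_nan() || trans.has_nan())
    stop("non-finite potentials (NaN)");
}

// [[Rcpp::export]]
double cpp_crf_score(const arma::mat& em, const arma::mat& trans,
                     const arma::ivec& y0) {
  check_pot(em, trans);
  const int m = em.n_rows, n = em.n_cols, S = n, E = n + 1;
  if ((int)y0.n_elem != m) stop("tag sequence length mismatch");
  if (y0.min() < 0 || y0.max() >= n) stop("tag index out of range");
  // additions are kept separate so that, for n = 1, the score follows the
  // exact floating-point grouping of the forward recursion (loss == 0)
  double s = trans(S, y0(0)) + em(0, y0(0));
  for (int t = 1; t < m; ++t) {
    s += trans(y0(t - 1), y0(t));
    s += em(t, y0(t));
  }
  s += trans(y0(m - 1), E);
  return s;
}

static mat crf_alphas(const mat& em, const mat& trans) {
  const int m = em.n_rows, n = em.n_cols, S = n;
  mat alpha(m, n);
  alpha.row(0) = trans.submat(S, 0, S, n - 1) + em.row(0);
  for (int t = 1; t < m; ++t)
    for (int j = 0; j < n; ++j)
      alpha(t, j) = lse(alpha.row(t - 1).t() + trans.submat(0, j, n - 1, j)) +
                    em(t, j);
  return alpha;
}

// [[Rcpp::export]]
double cpp_crf_logZ(const arma::mat& em, const arma::mat& trans) {
  check_pot(em, trans);
  const int m = em.n_rows, n = em.n_cols, E = n + 1;
  mat alpha = crf_alphas(em, trans);
  return lse(alpha.row(m - 1).t() + trans.submat(0, E, n - 1, E));
}

// [[Rcpp::export]]
List cpp_crf_viterbi(const arma::mat& em, const arma::mat& trans) {
  check_pot(em, trans);
  const int m = em.n_rows, n = em.n_cols, S = n, E = n + 1;
  mat delta(m, n);
  arma::imat psi(m, n, arma::fill::zeros);
  delta.row(0) = trans.submat(S, 0, S, n - 1) + em.row(0);
  for (int t = 1; t < m; ++t) {
    for (int j = 0; j < n; ++j) {
      int arg = 0;
      double best = delta(t - 1, 0) + trans(0, j);
      for (int i = 1; i < n; ++i) {           // ties keep the lowest index
        double v = delta(t - 1, i) + trans(i, j);
        if (v > best) { best = v; arg = i; }
      }
      delta(t, j) = best + em(t, j);
      psi(t, j) = arg;
    }
  }
  int arg = 0;
  double best = delta(m - 1, 0) + trans(0, E);
  for (int i = 1; i < n; ++i) {
    double v = delta(m - 1, i) + trans(i, E);
    if (v > best) { best = v; arg = i; }
  }
  IntegerVector path(m);
  path[m - 1] = arg;
  for (int t = m - 1; t > 0; --t) path[t - 1] = psi(t, path[t]);
  return List::create(_["path0"] = path, _["score"] = best);
}

// NLL loss and gradients wrt emissions and transitions
static double crf_loss_grad(const mat& em, const mat& trans,
                            const arma::ivec& y, mat& d_em, mat& d_trans) {
  const int m = em.n_rows, n = em.n_cols, S = n, E = n + 1;
  mat alpha = crf_alphas(em, trans);
  mat beta(m, n);
  beta.row(m - 1) = trans.submat(0, E, n - 1, E).t();
  for (int t = m - 2; t >= 0; --t)
    for (int i = 0; i < n; ++i)
      beta(t, i) = lse(trans.submat(i, 0, i, n - 1).t() +
                       em.row(t + 1).t() + beta.row(t + 1).t());
  double logZ = lse(alpha.row(m - 1).t() + trans.submat(0, E, n - 1, E));
  if (!std::isfinite(logZ)) stop("degenerate CRF: no admissible tag sequence");
  d_em = arma::exp(alpha + beta - logZ);  // state marginals
  for (int t = 0; t < m; ++t) d_em(t, y(t)) -= 1.0;
  // start transitions
  for (int j = 0; j < n; ++j) d_trans(S, j) += std::exp(alpha(0, j) + beta(0, j) - logZ);
  d_trans(S, y(0)) -= 1.0;
  // interior transitions: expected bigram counts
  for (int t = 0; t + 1 < m; ++t)
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j)
        d_trans(i, j) += std::exp(alpha(t, i) + trans(i, j) + em(t + 1, j) +
                                  beta(t + 1, j) - logZ);
  for (int t = 0; t + 1 < m; ++t) d_trans(y(t), y(t + 1)) -= 1.0;
  // end transitions
  for (int i = 0; i < n; ++i)
    d_trans(i, E) += std::exp(alpha(m - 1, i) + trans(i, E) - logZ);
  d_trans(y(m - 1), E) -= 1.0;
  return logZ - cpp_crf_score(em, trans, y);
}

// [[Rcpp::export]]
List cpp_crf_grad(const arma::mat& em, const arma::mat& trans,
                  const arma::ivec& y0) {
  check_pot(em, trans);
  mat d_em;
  mat d_trans(trans.n_rows, trans.n_cols, arma::fill::zeros);
  double loss = crf_loss_grad(em, trans, y0, d_em, d_trans);
  return List::create(_["loss"] = loss, _["d_emissions"] = d_em,
                      _["d_trans"] = d_trans);
}

// ---------------------------------------------------------------------------
// Exported encoder pieces (single sentence, explicit V)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_attention(const arma::mat& V, const arma::vec& w,
                   const arma::mat& Wv, const arma::mat& Wvh) {
  if (V.n_rows < 1) stop("attention requires m >= 1");
  mat A, C;
  cube T;
  attention_forward(V, w, Wv, Wvh, A, C, T);
  return List::create(_["weights"] = A, _["context"] = C);
}

// [[Rcpp::export]]
arma::mat cpp_lstm_forward(const arma::mat& X, const arma::mat& Wx,
                           const arma::mat& Wh, const arma::vec& b) {
  LstmCache ca;
  LstmWeights w{Wx, Wh, b};
  return lstm_forward(X, w, ca);
}

// [[Rcpp::export]]
List cpp_encode(const arma::mat& V, const List& params) {
  EncParams P = get_params(params);
  EncCache ca;
  mat em = encoder_forward(V, P, ca);
  return List::create(_["weights"] = ca.A, _["context"] = ca.C,
                      _["H"] = ca.H, _["L"] = ca.L, _["emissions"] = em);
}

static List grads_to_list(const EncGrads& G, bool with_trans) {
  List out = List::create(
      _["attn_w"] = G.attn_w, _["attn_Wv"] = G.attn_Wv,
      _["attn_Wvh"] = G.attn_Wvh,
      _["lstm1_fwd"] = List::create(_["Wx"] = G.l1f.Wx, _["Wh"] = G.l1f.Wh,
                                    _["b"] = G.l1f.b),
      _["lstm1_bwd"] = List::create(_["Wx"] = G.l1b.Wx, _["Wh"] = G.l1b.Wh,
                                    _["b"] = G.l1b.b),
      _["lstm2_fwd"] = List::create(_["Wx"] = G.l2f.Wx, _["Wh"] = G.l2f.Wh,
                                    _["b"] = G.l2f.b),
      _["lstm2_bwd"] = List::create(_["Wx"] = G.l2b.Wx, _["Wh"] = G.l2b.Wh,
                                    _["b"] = G.l2b.b),
      _["proj_W"] = G.proj_W, _["proj_b"] = G.proj_b);
  if (with_trans) out["trans"] = G.trans;
  return out;
}

// [[Rcpp::export]]
double cpp_sentence_loss(const arma::mat& V, const arma::ivec& y0,
                         const List& params) {
  EncParams P = get_params(params);
  EncCache ca;
  mat em = encoder_forward(V, P, ca);
  return cpp_crf_logZ(em, P.trans) - cpp_crf_score(em, P.trans, y0);
}

// [[Rcpp::export]]
List cpp_sentence_loss_grad(const arma::mat& V, const arma::ivec& y0,
                            const List& params) {
  EncParams P = get_params(params);
  EncGrads G;
  G.init(P);
  EncCache ca;
  mat em = encoder_forward(V, P, ca);
  mat d_em;
  double loss = crf_loss_grad(em, P.trans, y0, d_em, G.trans);
  mat dV = encoder_backward(V, P, ca, d_em, G);
  List g = grads_to_list(G, true);
  return List::create(_["loss"] = loss, _["grads"] = g, _["gV"] = dV);
}

// ---------------------------------------------------------------------------
// Batched training entry points (indices are 0-based; embeddings live in
// `params$emb_char` / `params$emb_pos` and V is assembled here)
// ---------------------------------------------------------------------------

static mat build_V(const IntegerVector& ci, const mat& Ec,
                   const IntegerVector* pi, const mat* Ep) {
  const int m = ci.size();
  const int l = Ec.n_cols;
  const int d = (pi != nullptr) ? l + (int)Ep->n_cols : l;
  mat V(m, d);
  for (int t = 0; t < m; ++t) {
    V(t, arma::span(0, l - 1)) = Ec.row(ci[t]);
    if (pi != nullptr)
      V(t, arma::span(l, d - 1)) = Ep->row((*pi)[t]);
  }
  return V;
}

// [[Rcpp::export]]
List cpp_batch_loss_grad(const List& chars, SEXP pos, const List& ys,
                         const List& params) {
  EncParams P = get_params(params);
  mat Ec = as<mat>(params["emb_char"]);
  bool has_pos = !Rf_isNull(pos);
  mat Ep;
  List posl;
  if (has_pos) {
    posl = as<List>(pos);
    Ep = as<mat>(params["emb_pos"]);
  }
  EncGrads G;
  G.init(P);
  mat gEc(Ec.n_rows, Ec.n_cols, arma::fill::zeros);
  mat gEp;
  if (has_pos) gEp.zeros(Ep.n_rows, Ep.n_cols);
  const int B = chars.size();
  NumericVector losses(B);
  double total = 0.0;
  for (int s = 0; s < B; ++s) {
    IntegerVector ci = chars[s];
    IntegerVector pi;
    if (has_pos) pi = posl[s];
    mat V = build_V(ci, Ec, has_pos ? &pi : nullptr, has_pos ? &Ep : nullptr);
    arma::ivec y = as<arma::ivec>(ys[s]);
    EncCache ca;
    mat em = encoder_forward(V, P, ca);
    mat d_em;
    double loss = crf_loss_grad(em, P.trans, y, d_em, G.trans);
    mat dV = encoder_backward(V, P, ca, d_em, G);
    const int l = Ec.n_cols;
    for (int t = 0; t < (int)V.n_rows; ++t) {
      gEc.row(ci[t]) += dV(t, arma::span(0, l - 1));
      if (has_pos) gEp.row(pi[t]) += dV(t, arma::span(l, V.n_cols - 1));
    }
    losses[s] = loss;
    total += loss;
  }
  List g = grads_to_list(G, true);
  g["emb_char"] = gEc;
  if (has_pos) g["emb_pos"] = gEp;
  return List::create(_["loss_sum"] = total, _["losses"] = losses,
                      _["grads"] = g);
}

// [[Rcpp::export]]
List cpp_predict_paths(const List& chars, SEXP pos, const List& params) {
  EncParams P = get_params(params);
  mat Ec = as<mat>(params["emb_char"]);
  bool has_pos = !Rf_isNull(pos);
  mat Ep;
  List posl;
  if (has_pos) {
    posl = as<List>(pos);
    Ep = as<mat>(params["emb_pos"]);
  }
  const int B = chars.size();
  List out(B);
  for (int s = 0; s < B; ++s) {
    IntegerVector ci = chars[s];
    IntegerVector pi;
    if (has_pos) pi = posl[s];
    mat V = build_V(ci, Ec, has_pos ? &pi : nullptr, has_pos ? &Ep : nullptr);
    EncCache ca;
    mat em = encoder_forward(V, P, ca);
    List vit = cpp_crf_viterbi(em, P.trans);
    out[s] = vit["path0"];
  }
  return out;
}
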