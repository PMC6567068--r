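// Training engine for the 1-D time-series classifiers (FCN, LSTM with
// dimension shuffle, LSTM-FCN, ALSTM-FCN).  Single precision, BLAS-backed.
// All randomness (init, dropout) is drawn from R's RNG so that results are
// reproducible under set.seed() on the R side.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;
using arma::fmat;
using arma::uword;

static const float BN_EPS = 1e-3f;   // Keras BatchNormalization default
static const float BN_MOM = 0.99f;    // running = mom*running + (1-mom)*batch

// ---------------------------------------------------------------- Adam ----

struct Adam {
  fmat m, v;
  void init(uword r, uword c) { m.zeros(r, c); v.zeros(r, c); }
};

static void adam_step(fmat& P, const fmat& G, Adam& a, float lr, int t) {
  const float b1 = 0.9f, b2 = 0.999f, eps = 1e-7f;
  a.m = b1 * a.m + (1.0f - b1) * G;
  a.v = b2 * a.v + (1.0f - b2) * (G % G);
  const float c1 = 1.0f - std::pow(b1, (float)t);
  const float c2 = 1.0f - std::pow(b2, (float)t);
  P -= lr * (a.m / c1) / (arma::sqrt(a.v / c2) + eps);
}

static fmat he_normal(uword r, uword c, float fan_in) {
  fmat W(r, c);
  const float sd = std::sqrt(2.0f / fan_in);
  for (uword i = 0; i < W.n_elem; ++i) W(i) = (float)R::norm_rand() * sd;
  return W;
}

static fmat glorot_uniform(uword r, uword c, float fan_in, float fan_out) {
  fmat W(r, c);
  const float lim = std::sqrt(6.0f / (fan_in + fan_out));
  for (uword i = 0; i < W.n_elem; ++i)
    W(i) = (float)(R::unif_rand() * 2.0 - 1.0) * lim;
  return W;
}

static fmat sigmoidf(const fmat& X) {
  fmat Y = X;
  Y.transform([](float x) { return 1.0f / (1.0f + std::exp(-x)); });
  return Y;
}

// ---------------------------------------------------- conv + BN + ReLU ----

struct ConvBlock {
  int k = 0, cin = 0, cout = 0, padL = 0;
  fmat W;                              // (k*cin) x cout, tap-major blocks
  fmat b, gamma, beta, rmean, rvar;    // 1 x cout
  Adam aW, ab, ag, abe;
  // caches (training mode)
  fmat Xin, xhat, out, mu, var_;
  // gradients
  fmat dW_, db_, dg_, dbe_;

  void init(int k_, int cin_, int cout_) {
    k = k_; cin = cin_; cout = cout_; padL = (k - 1) / 2;
    W = he_normal(k * cin, cout, (float)(k * cin));
    b.zeros(1, cout); gamma.ones(1, cout); beta.zeros(1, cout);
    rmean.zeros(1, cout); rvar.ones(1, cout);
    aW.init(k * cin, cout); ab.init(1, cout);
    ag.init(1, cout); abe.init(1, cout);
  }

  // guard-row padding isolates samples so each kernel tap is a single
  // batch-wide GEMM; shifted reads that cross a sample boundary land in
  // zero guard rows and contribute nothing
  static fmat pad_rows(const fmat& X, int N, int L, int G) {
    fmat P((size_t)N * (L + G), X.n_cols, arma::fill::zeros);
    for (int s = 0; s < N; ++s)
      P.rows((size_t)s * (L + G), (size_t)s * (L + G) + L - 1) =
        X.rows((size_t)s * L, (size_t)s * L + L - 1);
    return P;
  }

  static fmat unpad_rows(const fmat& P, int N, int L, int G) {
    fmat X((size_t)N * L, P.n_cols);
    for (int s = 0; s < N; ++s)
      X.rows((size_t)s * L, (size_t)s * L + L - 1) =
        P.rows((size_t)s * (L + G), (size_t)s * (L + G) + L - 1);
    return X;
  }

  fmat conv(const fmat& X, int N, int L) const {
    const int G = k;
    const fmat Xp = pad_rows(X, N, L, G);
    const size_t M = Xp.n_rows;
    fmat Yp(M, cout, arma::fill::zeros);
    for (int j = 0; j < k; ++j) {
      const int o = j - padL;                 // y[t] += x[t+o] * W_j
      const fmat Wj = W.rows((uword)j * cin, (uword)(j + 1) * cin - 1);
      if (o >= 0)
        Yp.rows(0, M - 1 - o) += Xp.rows(o, M - 1) * Wj;
      else
        Yp.rows(-o, M - 1) += Xp.rows(0, M - 1 + o) * Wj;
    }
    fmat Y = unpad_rows(Yp, N, L, G);
    Y.each_row() += b.row(0);
    return Y;
  }

  fmat forward(const fmat& X, int N, int L, bool training) {
    fmat Z = conv(X, N, L);
    if (training) {
      Xin = X;
      mu = arma::mean(Z, 0);
      var_ = arma::var(Z, 1, 0);             // population variance
      rmean = BN_MOM * rmean + (1.0f - BN_MOM) * mu;
      rvar = BN_MOM * rvar + (1.0f - BN_MOM) * var_;
      fmat inv = 1.0f / arma::sqrt(var_ + BN_EPS);
      Z.each_row() -= mu.row(0);
      Z.each_row() %= inv.row(0);
      xhat = Z;
      Z.each_row() %= gamma.row(0);
      Z.each_row() += beta.row(0);
      Z.transform([](float x) { return x > 0.0f ? x : 0.0f; });
      out = Z;
      return Z;
    }
    fmat inv = 1.0f / arma::sqrt(rvar + BN_EPS);
    Z.each_row() -= rmean.row(0);
    Z.each_row() %= inv.row(0);
    Z.each_row() %= gamma.row(0);
    Z.each_row() += beta.row(0);
    Z.transform([](float x) { return x > 0.0f ? x : 0.0f; });
    return Z;
  }

  // dOut -> dX (input gradient skipped when want_dx is false, i.e. layer 1)
  fmat backward(const fmat& dOut, int N, int L, bool want_dx) {
    fmat dY = dOut;
    dY.elem(arma::find(out <= 0.0f)).zeros();          // ReLU
    const float NL = (float)dY.n_rows;
    dg_ = arma::sum(dY % xhat, 0);
    dbe_ = arma::sum(dY, 0);
    fmat dxhat = dY;
    dxhat.each_row() %= gamma.row(0);
    fmat s1 = arma::sum(dxhat, 0);
    fmat s2 = arma::sum(dxhat % xhat, 0);
    fmat dZ = dxhat * NL;
    dZ.each_row() -= s1.row(0);
    fmat tmp = xhat;
    tmp.each_row() %= s2.row(0);
    dZ -= tmp;
    fmat invn = (1.0f / arma::sqrt(var_ + BN_EPS)) / NL;
    dZ.each_row() %= invn.row(0);
    // conv backward (same guard-row batching as the forward pass)
    db_ = arma::sum(dZ, 0);
    dW_.set_size(k * cin, cout);
    const int G = k;
    const fmat Xp = pad_rows(Xin, N, L, G);
    const fmat dZp = pad_rows(dZ, N, L, G);
    const size_t M = Xp.n_rows;
    fmat dXp;
    if (want_dx) dXp.zeros(M, cin);
    for (int j = 0; j < k; ++j) {
      const int o = j - padL;
      const fmat Wj = W.rows((uword)j * cin, (uword)(j + 1) * cin - 1);
      fmat dWj;
      if (o >= 0) {
        dWj = Xp.rows(o, M - 1).t() * dZp.rows(0, M - 1 - o);
        if (want_dx)
          dXp.rows(o, M - 1) += dZp.rows(0, M - 1 - o) * Wj.t();
      } else {
        dWj = Xp.rows(0, M - 1 + o).t() * dZp.rows(-o, M - 1);
        if (want_dx)
          dXp.rows(0, M - 1 + o) += dZp.rows(-o, M - 1) * Wj.t();
      }
      dW_.rows((uword)j * cin, (uword)(j + 1) * cin - 1) = dWj;
    }
    fmat dX;
    if (want_dx) dX = unpad_rows(dXp, N, L, G);
    return dX;
  }

  void apply(float lr, int t) {
    adam_step(W, dW_, aW, lr, t);
    adam_step(b, db_, ab, lr, t);
    adam_step(gamma, dg_, ag, lr, t);
    adam_step(beta, dbe_, abe, lr, t);
  }

  void clear_cache() {
    Xin.reset(); xhat.reset(); out.reset();
  }
};

// ------------------------------------------- LSTM branch (single step) ----
// Dimension shuffle: the length-L univariate trace is presented to the
// recurrent cell as one time step with L features, so the cell runs for a
// single step from a zero state (the recurrent kernel is inert and omitted).

struct LSTMBranch {
  int L = 0, H = 0;
  bool attention = false;
  float dropout = 0.8f;
  fmat Wl;         // 4H x L (gate order: i, f, g, o)
  fmat bl;         // 1 x 4H
  fmat wa, ba;     // 1 x L input-attention parameters
  Adam aWl, abl, awa, aba;
  // caches
  fmat X, A, Xe, Gi, Gf, Gg, Go, Th, mask;
  fmat dWl_, dbl_, dwa_, dba_;

  void init(int L_, int H_, bool att, float drop) {
    L = L_; H = H_; attention = att; dropout = drop;
    Wl = glorot_uniform(4 * H, L, (float)L, (float)(4 * H));
    bl.zeros(1, 4 * H);
    if (attention) {
      wa = he_normal(1, L, 10.0f);  // small init; uniform attention at start
      ba.zeros(1, L);
      awa.init(1, L); aba.init(1, L);
    }
    aWl.init(4 * H, L); abl.init(1, 4 * H);
  }

  fmat forward(const fmat& Xin, bool training) {
    fmat Xeff = Xin;
    if (attention) {
      fmat E = Xin;
      E.each_row() %= wa.row(0);
      E.each_row() += ba.row(0);
      fmat Aw(Xin.n_rows, L);
      for (uword s = 0; s < Xin.n_rows; ++s) {
        arma::frowvec e = E.row(s);
        e -= e.max();
        arma::frowvec ex = arma::exp(e);
        Aw.row(s) = ex / arma::accu(ex);
      }
      Xeff = (Aw % Xin) * (float)L;   // rescale so magnitudes stay O(x)
      if (training) { A = Aw; }
    }
    fmat G = Xeff * Wl.t();
    G.each_row() += bl.row(0);
    fmat gi = sigmoidf(G.cols(0, H - 1));
    fmat gf = sigmoidf(G.cols(H, 2 * H - 1));
    fmat gg = G.cols(2 * H, 3 * H - 1);
    gg.transform([](float x) { return std::tanh(x); });
    fmat go = sigmoidf(G.cols(3 * H, 4 * H - 1));
    fmat C = gi % gg;                 // zero initial state
    fmat th = C;
    th.transform([](float x) { return std::tanh(x); });
    fmat h = go % th;
    if (training) {
      X = Xin; Xe = Xeff; Gi = gi; Gf = gf; Gg = gg; Go = go; Th = th;
      mask.set_size(h.n_rows, h.n_cols);
      const float keep = 1.0f - dropout;
      for (uword i = 0; i < mask.n_elem; ++i)
        mask(i) = (R::unif_rand() < keep) ? 1.0f / keep : 0.0f;
      h %= mask;
    }
    return h;
  }

  fmat attention_weights(const fmat& Xin) const {
    fmat E = Xin;
    E.each_row() %= wa.row(0);
    E.each_row() += ba.row(0);
    fmat Aw(Xin.n_rows, L);
    for (uword s = 0; s < Xin.n_rows; ++s) {
      arma::frowvec e = E.row(s);
      e -= e.max();
      arma::frowvec ex = arma::exp(e);
      Aw.row(s) = ex / arma::accu(ex);
    }
    return Aw;
  }

  void backward(const fmat& dHout) {
    fmat dh = dHout % mask;
    fmat dgo = dh % Th;
    fmat dC = (dh % Go) % (1.0f - Th % Th);
    fmat dgi = dC % Gg;
    fmat dgg = dC % Gi;
    fmat dG(dh.n_rows, 4 * H);
    dG.cols(0, H - 1) = dgi % Gi % (1.0f - Gi);
    dG.cols(H, 2 * H - 1).zeros();          // forget gate inert (zero state)
    dG.cols(2 * H, 3 * H - 1) = dgg % (1.0f - Gg % Gg);
    dG.cols(3 * H, 4 * H - 1) = dgo % Go % (1.0f - Go);
    dWl_ = dG.t() * Xe;
    dbl_ = arma::sum(dG, 0);
    if (attention) {
      fmat dXe = dG * Wl;                    // N x L
      fmat dA = (dXe % X) * (float)L;
      // softmax backward per row
      fmat dE(dA.n_rows, L);
      for (uword s = 0; s < dA.n_rows; ++s) {
        const float dot = arma::accu(dA.row(s) % A.row(s));
        dE.row(s) = A.row(s) % (dA.row(s) - dot);
      }
      dwa_ = arma::sum(dE % X, 0);
      dba_ = arma::sum(dE, 0);
    }
  }

  void apply(float lr, int t) {
    adam_step(Wl, dWl_, aWl, lr, t);
    adam_step(bl, dbl_, abl, lr, t);
    if (attention) {
      adam_step(wa, dwa_, awa, lr, t);
      adam_step(ba, dba_, aba, lr, t);
    }
  }
};

// ----------------------------------------------------------- dense head ----

struct Dense {
  int F = 0, K = 0;
  fmat Wd, bd;
  Adam aW, ab;
  fmat feat, dWd_, dbd_;

  void init(int F_, int K_) {
    F = F_; K = K_;
    Wd = glorot_uniform(F, K, (float)F, (float)K);
    bd.zeros(1, K);
    aW.init(F, K); ab.init(1, K);
  }

  fmat forward(const fmat& X, bool training) {
    if (training) feat = X;
    fmat Z = X * Wd;
    Z.each_row() += bd.row(0);
    return Z;
  }

  fmat backward(const fmat& dZ) {
    dWd_ = feat.t() * dZ;
    dbd_ = arma::sum(dZ, 0);
    return dZ * Wd.t();
  }

  void apply(float lr, int t) {
    adam_step(Wd, dWd_, aW, lr, t);
    adam_step(bd, dbd_, ab, lr, t);
  }
};

// -------------------------------------------------------------- network ----

struct DeepNet {
  std::string kind;       // "lstm", "fcn", "lstm_fcn", "alstm_fcn"
  int L = 0, K = 0, H = 0;
  bool has_fcn = false, has_lstm = false;
  float dropout = 0.8f;
  ConvBlock c1, c2, c3;
  LSTMBranch lstm;
  Dense dense;
  int t_adam = 0;
  // cache for backward
  fmat gap_cache;

  void init(const std::string& kind_, int L_, int K_, int H_, float drop) {
    kind = kind_; L = L_; K = K_; H = H_; dropout = drop;
    has_fcn = (kind != "lstm");
    has_lstm = (kind != "fcn");
    int F = 0;
    if (has_fcn) {
      c1.init(8, 1, 128);
      c2.init(5, 128, 256);
      c3.init(3, 256, 128);
      F += 128;
    }
    if (has_lstm) {
      lstm.init(L, H, kind == "alstm_fcn", drop);
      F += H;
    }
    dense.init(F, K);
  }

  // X: N x L (scans in rows) -> NL x 1 sample-major column
  static fmat to_col(const fmat& X) {
    fmat Xt = X.t();                 // L x N, column s = trace s
    return fmat(Xt.memptr(), Xt.n_elem, 1);
  }

  fmat fcn_gap(const fmat& X, bool training) {
    const int N = X.n_rows;
    fmat a = c1.forward(to_col(X), N, L, training);
    a = c2.forward(a, N, L, training);
    a = c3.forward(a, N, L, training);
    fmat gap(N, c3.cout);
    for (int s = 0; s < N; ++s)
      gap.row(s) = arma::mean(a.rows((size_t)s * L, (size_t)s * L + L - 1), 0);
    return gap;
  }

  fmat logits(const fmat& X, bool training) {
    fmat feat;
    if (has_fcn) feat = fcn_gap(X, training);
    if (has_lstm) {
      fmat h = lstm.forward(X, training);
      feat = has_fcn ? arma::join_rows(feat, h) : h;
    }
    return dense.forward(feat, training);
  }

  static fmat softmax_rows(fmat Z) {
    for (uword s = 0; s < Z.n_rows; ++s) {
      arma::frowvec z = Z.row(s);
      z -= z.max();
      arma::frowvec e = arma::exp(z);
      Z.row(s) = e / arma::accu(e);
    }
    return Z;
  }

  double train_batch(const fmat& X, const arma::ivec& y,
                     const arma::fvec& w, float lr) {
    const int N = X.n_rows;
    fmat P = softmax_rows(logits(X, true));
    double loss = 0.0;
    fmat dZ = P;
    for (int i = 0; i < N; ++i) {
      const float p = std::max(P(i, y(i)), 1e-12f);
      loss += w(i) * -std::log(p);
      dZ(i, y(i)) -= 1.0f;
      dZ.row(i) *= w(i) / (float)N;
    }
    loss /= N;
    if (!std::isfinite(loss)) return loss;
    fmat dfeat = dense.backward(dZ);
    ++t_adam;
    if (has_fcn) {
      fmat dgap = dfeat.cols(0, 127);
      fmat d3((size_t)N * L, c3.cout);
      for (int s = 0; s < N; ++s)
        d3.rows((size_t)s * L, (size_t)s * L + L - 1) =
          arma::repmat(dgap.row(s) / (float)L, L, 1);
      fmat d2 = c3.backward(d3, N, L, true);
      fmat d1 = c2.backward(d2, N, L, true);
      c1.backward(d1, N, L, false);
      c1.apply(lr, t_adam); c2.apply(lr, t_adam); c3.apply(lr, t_adam);
      c1.clear_cache(); c2.clear_cache(); c3.clear_cache();
    }
    if (has_lstm) {
      fmat dh = has_fcn ? fmat(dfeat.cols(128, 128 + H - 1)) : dfeat;
      lstm.backward(dh);
      lstm.apply(lr, t_adam);
    }
    dense.apply(lr, t_adam);
    return loss;
  }

  // training-mode loss without a parameter update (for gradient checks)
  double loss_only(const fmat& X, const arma::ivec& y, const arma::fvec& w) {
    const int N = X.n_rows;
    fmat P = softmax_rows(logits(X, true));
    double loss = 0.0;
    for (int i = 0; i < N; ++i)
      loss += w(i) * -std::log(std::max(P(i, y(i)), 1e-12f));
    return loss / N;
  }

  // analytic gradients without applying the optimizer
  List gradients(const fmat& X, const arma::ivec& y, const arma::fvec& w) {
    const int N = X.n_rows;
    fmat P = softmax_rows(logits(X, true));
    fmat dZ = P;
    for (int i = 0; i < N; ++i) {
      dZ(i, y(i)) -= 1.0f;
      dZ.row(i) *= w(i) / (float)N;
    }
    fmat dfeat = dense.backward(dZ);
    List g;
    if (has_fcn) {
      fmat dgap = dfeat.cols(0, 127);
      fmat d3((size_t)N * L, c3.cout);
      for (int s = 0; s < N; ++s)
        d3.rows((size_t)s * L, (size_t)s * L + L - 1) =
          arma::repmat(dgap.row(s) / (float)L, L, 1);
      fmat d2 = c3.backward(d3, N, L, true);
      fmat d1 = c2.backward(d2, N, L, true);
      c1.backward(d1, N, L, false);
      ConvBlock* cb[3] = { &c1, &c2, &c3 };
      for (int i = 0; i < 3; ++i) {
        std::string s = std::to_string(i + 1);
        g["dW" + s] = cb[i]->dW_; g["db" + s] = cb[i]->db_;
        g["dg" + s] = cb[i]->dg_; g["dbe" + s] = cb[i]->dbe_;
      }
    }
    if (has_lstm) {
      fmat dh = has_fcn ? fmat(dfeat.cols(128, 128 + H - 1)) : dfeat;
      lstm.backward(dh);
      g["dWl"] = lstm.dWl_; g["dbl"] = lstm.dbl_;
      if (lstm.attention) { g["dwa"] = lstm.dwa_; g["dba"] = lstm.dba_; }
    }
    g["dWd"] = dense.dWd_; g["dbd"] = dense.dbd_;
    return g;
  }

  fmat predict(const fmat& X) {
    const int N = X.n_rows, chunk = 64;
    fmat P(N, K);
    for (int s0 = 0; s0 < N; s0 += chunk) {
      const int s1 = std::min(N, s0 + chunk) - 1;
      P.rows(s0, s1) = softmax_rows(logits(X.rows(s0, s1), false));
    }
    return P;
  }

  // final conv block activations (eval mode) for one trace: L x 128
  fmat conv_features(const fmat& x) {
    fmat a = c1.forward(to_col(x), 1, L, false);
    a = c2.forward(a, 1, L, false);
    return c3.forward(a, 1, L, false);
  }
};

// ------------------------------------------------------------ R bridge ----

static DeepNet* get_net(SEXP ptr) {
  XPtr<DeepNet> p(ptr);
  return p.get();
}

static fmat as_fmat(const NumericMatrix& X) {
  fmat Y(X.nrow(), X.ncol());
  for (int j = 0; j < X.ncol(); ++j)
    for (int i = 0; i < X.nrow(); ++i)
      Y(i, j) = (float)X(i, j);
  return Y;
}

static NumericMatrix as_rmat(const fmat& X) {
  NumericMatrix Y(X.n_rows, X.n_cols);
  for (uword j = 0; j < X.n_cols; ++j)
    for (uword i = 0; i < X.n_rows; ++i)
      Y(i, j) = X(i, j);
  return Y;
}

// [[Rcpp::export]]
SEXP nn_new(std::string kind, int L, int K, int cells, double dropout) {
  DeepNet* net = new DeepNet();
  net->init(kind, L, K, cells, (float)dropout);
  XPtr<DeepNet> ptr(net, true);
  return ptr;
}

// [[Rcpp::export]]
double nn_train_batch(SEXP ptr, NumericMatrix X, IntegerVector y,
                      NumericVector w, double lr) {
  DeepNet* net = get_net(ptr);
  arma::ivec yy(y.size());
  arma::fvec ww(w.size());
  for (int i = 0; i < y.size(); ++i) { yy(i) = y[i]; ww(i) = (float)w[i]; }
  return net->train_batch(as_fmat(X), yy, ww, (float)lr);
}

// [[Rcpp::export]]
double nn_loss(SEXP ptr, NumericMatrix X, IntegerVector y, NumericVector w) {
  DeepNet* net = get_net(ptr);
  arma::ivec yy(y.size());
  arma::fvec ww(w.size());
  for (int i = 0; i < y.size(); ++i) { yy(i) = y[i]; ww(i) = (float)w[i]; }
  return net->loss_only(as_fmat(X), yy, ww);
}

// [[Rcpp::export]]
List nn_gradients(SEXP ptr, NumericMatrix X, IntegerVector y,
                  NumericVector w) {
  DeepNet* net = get_net(ptr);
  arma::ivec yy(y.size());
  arma::fvec ww(w.size());
  for (int i = 0; i < y.size(); ++i) { yy(i) = y[i]; ww(i) = (float)w[i]; }
  return net->gradients(as_fmat(X), yy, ww);
}

// [[Rcpp::export]]
NumericMatrix nn_predict(SEXP ptr, NumericMatrix X) {
  return as_rmat(get_net(ptr)->predict(as_fmat(X)));
}

// [[Rcpp::export]]
NumericMatrix nn_conv_features(SEXP ptr, NumericVector x) {
  DeepNet* net = get_net(ptr);
  if (!net->has_fcn) stop("model has no convolutional branch");
  fmat xr(1, x.size());
  for (int i = 0; i < x.size(); ++i) xr(0, i) = (float)x[i];
  return as_rmat(net->conv_features(xr));
}

// [[Rcpp::export]]
NumericMatrix nn_attention(SEXP ptr, NumericMatrix X) {
  DeepNet* net = get_net(ptr);
  if (!(net->has_lstm && net->lstm.attention))
    stop("model has no attention branch");
  return as_rmat(net->lstm.attention_weights(as_fmat(X)));
}

// [[Rcpp::export]]
List nn_info(SEXP ptr) {
  DeepNet* net = get_net(ptr);
  return List::create(
    _["kind"] = net->kind, _["length"] = net->L, _["n_classes"] = net->K,
    _["cells"] = net->H, _["dropout"] = net->dropout,
    _["fcn_dim"] = net->has_fcn ? 128 : 0,
    _["lstm_dim"] = net->has_lstm ? net->H : 0,
    _["lstm_steps"] = net->has_lstm ? 1 : 0);
}

// [[Rcpp::export]]
List nn_dense_info(SEXP ptr) {
  DeepNet* net = get_net(ptr);
  return List::create(
    _["W"] = as_rmat(net->dense.Wd), _["b"] = as_rmat(net->dense.bd),
    _["fcn_dim"] = net->has_fcn ? 128 : 0,
    _["lstm_dim"] = net->has_lstm ? net->H : 0);
}

// [[Rcpp::export]]
List nn_state_get(SEXP ptr) {
  DeepNet* net = get_net(ptr);
  List st;
  st["kind"] = net->kind; st["L"] = net->L; st["K"] = net->K;
  st["H"] = net->H; st["dropout"] = net->dropout;
  if (net->has_fcn) {
    ConvBlock* cb[3] = { &net->c1, &net->c2, &net->c3 };
    for (int i = 0; i < 3; ++i) {
      std::string s = std::to_string(i + 1);
      st["W" + s] = as_rmat(cb[i]->W);     st["b" + s] = as_rmat(cb[i]->b);
      st["g" + s] = as_rmat(cb[i]->gamma); st["be" + s] = as_rmat(cb[i]->beta);
      st["rm" + s] = as_rmat(cb[i]->rmean); st["rv" + s] = as_rmat(cb[i]->rvar);
    }
  }
  if (net->has_lstm) {
    st["Wl"] = as_rmat(net->lstm.Wl); st["bl"] = as_rmat(net->lstm.bl);
    if (net->lstm.attention) {
      st["wa"] = as_rmat(net->lstm.wa); st["ba"] = as_rmat(net->lstm.ba);
    }
  }
  st["Wd"] = as_rmat(net->dense.Wd); st["bd"] = as_rmat(net->dense.bd);
  return st;
}

// [[Rcpp::export]]
SEXP nn_from_state(List st) {
  DeepNet* net = new DeepNet();
  net->init(as<std::string>(st["kind"]), as<int>(st["L"]), as<int>(st["K"]),
            as<int>(st["H"]), (float)as<double>(st["dropout"]));
  if (net->has_fcn) {
    ConvBlock* cb[3] = { &net->c1, &net->c2, &net->c3 };
    for (int i = 0; i < 3; ++i) {
      std::string s = std::to_string(i + 1);
      cb[i]->W = as_fmat(st["W" + s]);     cb[i]->b = as_fmat(st["b" + s]);
      cb[i]->gamma = as_fmat(st["g" + s]); cb[i]->beta = as_fmat(st["be" + s]);
      cb[i]->rmean = as_fmat(st["rm" + s]); cb[i]->rvar = as_fmat(st["rv" + s]);
    }
  }
  if (net->has_lstm) {
    net->lstm.Wl = as_fmat(st["Wl"]); net->lstm.bl = as_fmat(st["bl"]);
    if (net->lstm.attention) {
      net->lstm.wa = as_fmat(st["wa"]); net->lstm.ba = as_fmat(st["ba"]);
    }
  }
  net->dense.Wd = as_fmat(st["Wd"]); net->dense.bd = as_fmat(st["bd"]);
  XPtr<DeepNet> ptr(net, true);
  return ptr;
}

// [[Rcpp::export]]
double nn_n_params(SEXP ptr) {
  DeepNet* net = get_net(ptr);
  double n = net->dense.Wd.n_elem + net->dense.bd.n_elem;
  if (net->has_fcn) {
    ConvBlock* cb[3] = { &net->c1, &net->c2, &net->c3 };
    for (int i = 0; i < 3; ++i)
      n += cb[i]->W.n_elem + cb[i]->b.n_elem + 2 * cb[i]->gamma.n_elem;
  }
  if (net->has_lstm) {
    n += net->lstm.Wl.n_elem + net->lstm.bl.n_elem;
    if (net->lstm.attention) n += net->lstm.wa.n_elem + net->lstm.ba.n_elem;
  }
  return n;
}
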