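// Masked LSTM (clamp semantics) + dense sigmoid readout, trained with Adam
// on mean squared error of the final-valid-step prediction.
//
// Data layout: inputs arrive as an arma::cube of dimension (F, N, T) --
// slice t is the F x N matrix of all tokens at time t -- with a per-token
// valid length. Frames at or beyond a token's valid length leave the
// hidden and cell state unchanged (state clamping), so the final-step
// readout is invariant to trailing padding to machine precision.
//
// Weights: Wx (4H x F), Wh (4H x H), b (4H), Wd (O x H), bd (O).
// Gate row blocks in order: input, forget, candidate, output.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline fmat sigmoidf(const fmat& z) { return 1.0f / (1.0f + exp(-z)); }

struct Weights {
  fmat Wx, Wh, Wd;
  fvec b, bd;
};

static Weights as_weights(const Rcpp::List& w) {
  Weights W;
  W.Wx = conv_to<fmat>::from(Rcpp::as<mat>(w["Wx"]));
  W.Wh = conv_to<fmat>::from(Rcpp::as<mat>(w["Wh"]));
  W.b  = conv_to<fvec>::from(Rcpp::as<vec>(w["b"]));
  W.Wd = conv_to<fmat>::from(Rcpp::as<mat>(w["Wd"]));
  W.bd = conv_to<fvec>::from(Rcpp::as<vec>(w["bd"]));
  return W;
}

static Rcpp::List weights_out(const Weights& W) {
  return Rcpp::List::create(
    Rcpp::Named("Wx") = conv_to<mat>::from(W.Wx),
    Rcpp::Named("Wh") = conv_to<mat>::from(W.Wh),
    Rcpp::Named("b")  = conv_to<vec>::from(W.b),
    Rcpp::Named("Wd") = conv_to<mat>::from(W.Wd),
    Rcpp::Named("bd") = conv_to<vec>::from(W.bd));
}

// forward pass over a (F, N, T) cube; returns final hidden state and,
// optionally, the full clamped hidden trajectory (H, N, T)
static void lstm_forward(const Weights& W, const fcube& X,
                         const ivec& len, int T_use,
                         fmat& Hfin, fcube* traj) {
  const int H = W.Wh.n_cols, N = X.n_cols, F = X.n_rows;
  fmat Xm(const_cast<float*>(X.memptr()), F, X.n_cols * X.n_slices, false);
  fmat Zall = W.Wx * Xm.cols(0, (uword)N * T_use - 1);
  Zall.each_col() += W.b;
  fmat h(H, N, fill::zeros), c(H, N, fill::zeros);
  fmat cn(H, N), hn(H, N);
  for (int t = 0; t < T_use; ++t) {
    fmat Zt(Zall.colptr((uword)t * N), 4 * H, N, false);
    Zt += W.Wh * h;
    fmat I = sigmoidf(Zt.rows(0, H - 1));
    fmat Fg = sigmoidf(Zt.rows(H, 2 * H - 1));
    fmat G = tanh(Zt.rows(2 * H, 3 * H - 1));
    fmat O = sigmoidf(Zt.rows(3 * H, 4 * H - 1));
    cn = Fg % c + I % G;
    hn = O % tanh(cn);
    // clamp: invalid frames keep previous state exactly
    for (int j = 0; j < N; ++j) {
      if (t < len(j)) { c.col(j) = cn.col(j); h.col(j) = hn.col(j); }
    }
    if (traj) traj->slice(t) = h;
  }
  Hfin = h;
}

static fmat dense_sigmoid(const Weights& W, const fmat& Hfin) {
  fmat P = W.Wd * Hfin;
  P.each_col() += W.bd;
  return sigmoidf(P);
}

// mean cosine between predicted and target columns
static double mean_cosine(const fmat& P, const fmat& Y) {
  vec cs(P.n_cols);
  for (uword j = 0; j < P.n_cols; ++j) {
    double np = norm(P.col(j)), ny = norm(Y.col(j));
    cs(j) = (np > 0 && ny > 0) ? dot(P.col(j), Y.col(j)) / (np * ny) : 0.0;
  }
  return mean(cs);
}

struct Grads {
  fmat Wx, Wh, Wd;
  fvec b, bd;
  double loss;
};

// forward + BPTT on one batch; loss = mean over (O * N) squared errors.
// The input projection is one large GEMM over all timesteps; gate
// activations live in preallocated cubes; the weight gradients dWx and
// dWh are single GEMMs against the stacked inputs / shifted hidden
// states.
static Grads batch_grad(const Weights& W, const fcube& X, const ivec& len,
                        const fmat& Y) {
  const int H = W.Wh.n_cols, N = X.n_cols, F = X.n_rows;
  const int T = len.max();
  fmat Xm(const_cast<float*>(X.memptr()), F, X.n_cols * X.n_slices, false);
  fmat Zall = W.Wx * Xm.cols(0, (uword)N * T - 1);   // 4H x N*T
  Zall.each_col() += W.b;
  fcube Ic(H, N, T), Fc(H, N, T), Gc(H, N, T), Oc(H, N, T),
        Cc(H, N, T), Tc(H, N, T), Hsh(H, N, T);      // Hsh: h_{t-1}
  fmat mask(N, T);
  fmat h(H, N, fill::zeros), c(H, N, fill::zeros);
  fmat cn(H, N), hn(H, N);
  for (int t = 0; t < T; ++t) {
    Hsh.slice(t) = h;
    fmat Zt(Zall.colptr((uword)t * N), 4 * H, N, false);
    Zt += W.Wh * h;
    fmat& I = Ic.slice(t);
    fmat& Fg = Fc.slice(t);
    fmat& G = Gc.slice(t);
    fmat& O = Oc.slice(t);
    I = sigmoidf(Zt.rows(0, H - 1));
    Fg = sigmoidf(Zt.rows(H, 2 * H - 1));
    G = tanh(Zt.rows(2 * H, 3 * H - 1));
    O = sigmoidf(Zt.rows(3 * H, 4 * H - 1));
    cn = Fg % c + I % G;
    hn = O % tanh(cn);
    for (int j = 0; j < N; ++j) {
      bool v = t < len(j);
      mask(j, t) = v ? 1.0f : 0.0f;
      if (v) { c.col(j) = cn.col(j); h.col(j) = hn.col(j); }
    }
    Cc.slice(t) = c;
    Tc.slice(t) = tanh(c);
  }
  fmat P = dense_sigmoid(W, h);
  fmat E = P - Y;
  double loss = accu(square(conv_to<mat>::from(E))) / (E.n_elem);

  Grads Gd;
  fmat dP = (2.0f / (float)E.n_elem) * E;
  fmat dZd = dP % P % (1.0f - P);
  Gd.Wd = dZd * h.t();
  Gd.bd = sum(dZd, 1);
  fmat dh = W.Wd.t() * dZd;           // gradient w.r.t. clamped final state
  fmat dc(H, N, fill::zeros);
  fcube dZ(4 * H, N, T);
  fmat dct(H, N), cprev0(H, N, fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    frowvec m = mask.col(t).t();
    frowvec minv = 1.0f - m;
    const fmat& I = Ic.slice(t);
    const fmat& Fg = Fc.slice(t);
    const fmat& G = Gc.slice(t);
    const fmat& O = Oc.slice(t);
    const fmat& tn = Tc.slice(t);
    const fmat& cprev = (t > 0) ? Cc.slice(t - 1) : cprev0;
    dct = dc + dh % O % (1.0f - square(tn));
    fmat dZt(dZ.slice_memptr(t), 4 * H, N, false);
    dZt.rows(0, H - 1) = (dct % G) % I % (1.0f - I);
    dZt.rows(H, 2 * H - 1) = (dct % cprev) % Fg % (1.0f - Fg);
    dZt.rows(2 * H, 3 * H - 1) = (dct % I) % (1.0f - square(G));
    dZt.rows(3 * H, 4 * H - 1) = (dh % tn) % O % (1.0f - O);
    // zero gradients on invalid frames (state passed through unchanged)
    dZt.each_row() %= m;
    fmat dh_pass = dh;
    dh_pass.each_row() %= minv;                // pass-through when invalid
    dh = W.Wh.t() * dZt + dh_pass;
    fmat dc_cell = dct % Fg;
    dc_cell.each_row() %= m;
    dc.each_row() %= minv;
    dc += dc_cell;
  }
  fmat dZm(dZ.memptr(), 4 * H, (uword)N * T, false);
  fmat Hm(Hsh.memptr(), H, (uword)N * T, false);
  Gd.Wx = dZm * Xm.cols(0, (uword)N * T - 1).t();
  Gd.Wh = dZm * Hm.t();
  Gd.b = sum(dZm, 1);
  Gd.loss = loss;
  return Gd;
}

// [[Rcpp::export]]
Rcpp::List cpp_lstm_forward(const Rcpp::List& weights, const arma::cube& x,
                            const arma::ivec& len, bool return_hidden) {
  Weights W = as_weights(weights);
  fcube X = conv_to<fcube>::from(x);
  const int T = X.n_slices, N = X.n_cols, H = W.Wh.n_cols;
  fmat Hfin;
  fcube traj;
  if (return_hidden) traj.set_size(H, N, T);
  lstm_forward(W, X, len, T, Hfin, return_hidden ? &traj : nullptr);
  fmat P = dense_sigmoid(W, Hfin);
  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("prediction") = conv_to<mat>::from(P),
    Rcpp::Named("final_hidden") = conv_to<mat>::from(Hfin));
  if (return_hidden) out["hidden"] = conv_to<cube>::from(traj);
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_lstm_grad(const Rcpp::List& weights, const arma::cube& x,
                         const arma::ivec& len, const arma::mat& y) {
  Weights W = as_weights(weights);
  fcube X = conv_to<fcube>::from(x);
  fmat Y = conv_to<fmat>::from(y);
  Grads g = batch_grad(W, X, len, Y);
  return Rcpp::List::create(
    Rcpp::Named("loss") = g.loss,
    Rcpp::Named("Wx") = conv_to<mat>::from(g.Wx),
    Rcpp::Named("Wh") = conv_to<mat>::from(g.Wh),
    Rcpp::Named("b") = conv_to<vec>::from(g.b),
    Rcpp::Named("Wd") = conv_to<mat>::from(g.Wd),
    Rcpp::Named("bd") = conv_to<vec>::from(g.bd));
}

// [[Rcpp::export]]
double cpp_lstm_loss(const Rcpp::List& weights, const arma::cube& x,
                     const arma::ivec& len, const arma::mat& y) {
  Weights W = as_weights(weights);
  fcube X = conv_to<fcube>::from(x);
  const int T = X.n_slices;
  fmat Hfin;
  lstm_forward(W, X, len, T, Hfin, nullptr);
  fmat P = dense_sigmoid(W, Hfin);
  fmat E = P - conv_to<fmat>::from(y);
  return accu(square(conv_to<mat>::from(E))) / E.n_elem;
}

struct Adam {
  fmat mWx, vWx, mWh, vWh, mWd, vWd;
  fvec mb, vb, mbd, vbd;
  long step = 0;
  void init(const Weights& W) {
    mWx.zeros(size(W.Wx)); vWx.zeros(size(W.Wx));
    mWh.zeros(size(W.Wh)); vWh.zeros(size(W.Wh));
    mWd.zeros(size(W.Wd)); vWd.zeros(size(W.Wd));
    mb.zeros(size(W.b)); vb.zeros(size(W.b));
    mbd.zeros(size(W.bd)); vbd.zeros(size(W.bd));
  }
  template <class M>
  void upd1(M& w, M& m, M& v, const M& g, float lr, float c1, float c2) {
    m = 0.9f * m + 0.1f * g;
    v = 0.999f * v + 0.001f * square(g);
    w -= lr * (m / c1) / (sqrt(v / c2) + 1e-8f);
  }
  void update(Weights& W, const Grads& g, float lr) {
    ++step;
    float c1 = 1.0f - std::pow(0.9f, (float)step);
    float c2 = 1.0f - std::pow(0.999f, (float)step);
    upd1(W.Wx, mWx, vWx, g.Wx, lr, c1, c2);
    upd1(W.Wh, mWh, vWh, g.Wh, lr, c1, c2);
    upd1(W.Wd, mWd, vWd, g.Wd, lr, c1, c2);
    upd1(W.b, mb, vb, g.b, lr, c1, c2);
    upd1(W.bd, mbd, vbd, g.bd, lr, c1, c2);
  }
};

static double set_cosine(const Weights& W, const fcube& X, const ivec& len,
                         const fmat& Y, const uvec& idx, int chunk) {
  if (idx.n_elem == 0) return NA_REAL;
  double acc = 0;
  const int T = X.n_slices;
  for (uword s = 0; s < idx.n_elem; s += chunk) {
    uword e = std::min<uword>(s + chunk, idx.n_elem) - 1;
    uvec ii = idx.subvec(s, e);
    fcube Xb(X.n_rows, ii.n_elem, T);
    ivec lb(ii.n_elem);
    for (uword j = 0; j < ii.n_elem; ++j) lb(j) = len(ii(j));
    int Tb = lb.max();
    for (int t = 0; t < Tb; ++t) Xb.slice(t) = X.slice(t).cols(ii);
    fmat Hfin;
    lstm_forward(W, Xb, lb, Tb, Hfin, nullptr);
    fmat P = dense_sigmoid(W, Hfin);
    acc += mean_cosine(P, Y.cols(ii)) * ii.n_elem;
  }
  return acc / idx.n_elem;
}

// [[Rcpp::export]]
Rcpp::List cpp_lstm_train(const Rcpp::List& weights, const arma::cube& x,
                          const arma::ivec& len, const arma::mat& y,
                          const arma::uvec& train_idx,
                          const arma::uvec& val_idx,
                          int epochs, int batch_size, double lr,
                          int checkpoint_interval, int seed,
                          bool verbose) {
  Weights W = as_weights(weights);
  fcube X = conv_to<fcube>::from(x);
  fmat Y = conv_to<fmat>::from(y);
  Adam opt;
  opt.init(W);
  std::mt19937 rng(seed);
  std::vector<uword> order(train_idx.begin(), train_idx.end());
  const int n_check = epochs / checkpoint_interval;
  mat history(n_check, 4);
  Weights best = W;
  double best_val = -datum::inf;
  int best_epoch = 0, row = 0;
  for (int ep = 1; ep <= epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double ep_loss = 0;
    int nb = 0;
    for (size_t s = 0; s < order.size(); s += batch_size) {
      size_t e = std::min(s + batch_size, order.size());
      uvec ii(e - s);
      for (size_t j = s; j < e; ++j) ii(j - s) = order[j];
      ivec lb(ii.n_elem);
      for (uword j = 0; j < ii.n_elem; ++j) lb(j) = len(ii(j));
      int Tb = lb.max();
      fcube Xb(X.n_rows, ii.n_elem, Tb);
      for (int t = 0; t < Tb; ++t) Xb.slice(t) = X.slice(t).cols(ii);
      Grads g = batch_grad(W, Xb, lb, Y.cols(ii));
      if (!std::isfinite(g.loss))
        Rcpp::stop("training diverged to non-finite loss at epoch %d", ep);
      opt.update(W, g, (float)lr);
      ep_loss += g.loss;
      ++nb;
    }
    if (ep % checkpoint_interval == 0) {
      double tc = set_cosine(W, X, len, Y, train_idx, batch_size);
      double vc = set_cosine(W, X, len, Y, val_idx, batch_size);
      history(row, 0) = ep;
      history(row, 1) = ep_loss / nb;
      history(row, 2) = tc;
      history(row, 3) = vc;
      ++row;
      double crit = val_idx.n_elem ? vc : tc;
      if (std::isfinite(crit) && crit > best_val) {
        best_val = crit;
        best = W;
        best_epoch = ep;
      }
      if (verbose)
        Rcpp::Rcout << "epoch " << ep << " loss " << ep_loss / nb
                    << " train_cos " << tc << " val_cos " << vc << "\n";
      Rcpp::checkUserInterrupt();
    }
  }
  return Rcpp::List::create(
    Rcpp::Named("weights") = weights_out(W),
    Rcpp::Named("best_weights") = weights_out(best),
    Rcpp::Named("best_epoch") = best_epoch,
    Rcpp::Named("history") = history);
}
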