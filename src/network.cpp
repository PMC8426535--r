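// Forward model and training core: 2-layer bidirectional LSTM ->
// multi-head self-attention -> dense -> 8 x n_org score matrix with
// column max-pooling, plus analytic backpropagation and Adam updates.
//
// Computation runs over the unmasked (valid) positions only; because
// padding is always a C-terminal suffix of all-zero masked rows, running
// the recurrence over the valid prefix is exactly equivalent to masked
// computation over the full encoding length.  Single-threaded and fully
// deterministic given the seed.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;
using Rcpp::Named;

static const char* PARAM_NAMES[16] = {
  "l1f.W", "l1f.U", "l1f.b", "l1b.W", "l1b.U", "l1b.b",
  "l2f.W", "l2f.U", "l2f.b", "l2b.W", "l2b.U", "l2b.b",
  "Ws1", "Ws2", "Wd", "bd"
};
static const int N_PARAMS = 16;

static std::vector<mat> params_from_list(const List& p) {
  std::vector<mat> out(N_PARAMS);
  for (int i = 0; i < N_PARAMS; ++i)
    out[i] = Rcpp::as<mat>(p[PARAM_NAMES[i]]);
  return out;
}

static List params_to_list(const std::vector<mat>& v) {
  List out(N_PARAMS);
  Rcpp::CharacterVector nm(N_PARAMS);
  for (int i = 0; i < N_PARAMS; ++i) { out[i] = v[i]; nm[i] = PARAM_NAMES[i]; }
  out.attr("names") = nm;
  return out;
}

struct LSTMCache {
  mat i, f, g, o, c, tc, h;  // u x n each
  bool fwd;
};

// One LSTM direction over input X (in_dim x n).  Gate block order: i,f,g,o.
static mat lstm_forward(const mat& W, const mat& U, const vec& b,
                        const mat& X, bool fwd, LSTMCache& C) {
  const uword u = U.n_cols, n = X.n_cols;
  C.i.set_size(u, n); C.f.set_size(u, n); C.g.set_size(u, n);
  C.o.set_size(u, n); C.c.set_size(u, n); C.tc.set_size(u, n);
  C.h.set_size(u, n); C.fwd = fwd;
  vec h_prev(u, fill::zeros), c_prev(u, fill::zeros);
  for (uword k = 0; k < n; ++k) {
    uword t = fwd ? k : (n - 1 - k);
    vec a = W * X.col(t) + U * h_prev + b;
    vec ig = 1.0 / (1.0 + exp(-a.subvec(0, u - 1)));
    vec fg = 1.0 / (1.0 + exp(-a.subvec(u, 2 * u - 1)));
    vec gg = tanh(a.subvec(2 * u, 3 * u - 1));
    vec og = 1.0 / (1.0 + exp(-a.subvec(3 * u, 4 * u - 1)));
    vec cc = fg % c_prev + ig % gg;
    vec tc = tanh(cc);
    vec hh = og % tc;
    C.i.col(t) = ig; C.f.col(t) = fg; C.g.col(t) = gg; C.o.col(t) = og;
    C.c.col(t) = cc; C.tc.col(t) = tc; C.h.col(t) = hh;
    h_prev = hh; c_prev = cc;
  }
  return C.h;
}

// BPTT for one direction.  dH: u x n upstream gradient on outputs.
// Accumulates dW,dU,db and returns gradient w.r.t. the input sequence.
static mat lstm_backward(const mat& W, const mat& U,
                         const mat& X, const LSTMCache& C, const mat& dH,
                         mat& dW, mat& dU, vec& db) {
  const uword u = U.n_cols, n = X.n_cols;
  mat dX(X.n_rows, n, fill::zeros);
  vec dh_next(u, fill::zeros), dc_next(u, fill::zeros);
  for (uword k = 0; k < n; ++k) {
    uword t = C.fwd ? (n - 1 - k) : k;  // reverse of forward order
    bool first = C.fwd ? (t == 0) : (t == n - 1);
    vec h_prev = first ? vec(u, fill::zeros)
                       : vec(C.h.col(C.fwd ? t - 1 : t + 1));
    vec c_prev = first ? vec(u, fill::zeros)
                       : vec(C.c.col(C.fwd ? t - 1 : t + 1));
    vec dh = dH.col(t) + dh_next;
    vec do_ = dh % C.tc.col(t);
    vec dc = dc_next + dh % C.o.col(t) % (1.0 - square(C.tc.col(t)));
    vec di = dc % C.g.col(t);
    vec dg = dc % C.i.col(t);
    vec df = dc % c_prev;
    vec da(4 * u);
    da.subvec(0, u - 1)         = di % C.i.col(t) % (1.0 - C.i.col(t));
    da.subvec(u, 2 * u - 1)     = df % C.f.col(t) % (1.0 - C.f.col(t));
    da.subvec(2 * u, 3 * u - 1) = dg % (1.0 - square(C.g.col(t)));
    da.subvec(3 * u, 4 * u - 1) = do_ % C.o.col(t) % (1.0 - C.o.col(t));
    dW += da * X.col(t).t();
    dU += da * h_prev.t();
    db += da;
    dX.col(t) += W.t() * da;
    dh_next = U.t() * da;
    dc_next = dc % C.f.col(t);
  }
  return dX;
}

struct FwdCache {
  mat X;                       // F x n input
  LSTMCache l1f, l1b, l2f, l2b;
  mat H1, H1d, H2, H2d;        // 2u x n
  mat T, A, M;                 // d_a x n, r x n, r x 2u
  vec m_flat, m_drop, z, p, org;
  uvec org_arg;
  mat mask1, mask2;            // dropout masks
  vec mask3;
};

static void forward_full(const std::vector<mat>& P, const mat& X, int n_org,
                         bool training, double drop_lstm, double drop_dense,
                         std::mt19937_64& rng, FwdCache& C) {
  const mat &W1f = P[0], &U1f = P[1]; const vec b1f = P[2].col(0);
  const mat &W1b = P[3], &U1b = P[4]; const vec b1b = P[5].col(0);
  const mat &W2f = P[6], &U2f = P[7]; const vec b2f = P[8].col(0);
  const mat &W2b = P[9], &U2b = P[10]; const vec b2b = P[11].col(0);
  const mat &Ws1 = P[12], &Ws2 = P[13], &Wd = P[14]; const vec bd = P[15].col(0);
  const uword n = X.n_cols;
  if (n == 0) Rcpp::stop("all positions are masked: nothing to encode");

  C.X = X;
  mat Hf1 = lstm_forward(W1f, U1f, b1f, X, true, C.l1f);
  mat Hb1 = lstm_forward(W1b, U1b, b1b, X, false, C.l1b);
  C.H1 = join_cols(Hf1, Hb1);

  std::uniform_real_distribution<double> unif(0.0, 1.0);
  auto make_mask = [&](uword nr, uword nc, double pdrop) {
    mat msk(nr, nc, fill::ones);
    if (training && pdrop > 0) {
      for (uword j = 0; j < nc; ++j)
        for (uword i = 0; i < nr; ++i)
          msk(i, j) = (unif(rng) < pdrop) ? 0.0 : 1.0 / (1.0 - pdrop);
    }
    return msk;
  };
  C.mask1 = make_mask(C.H1.n_rows, n, drop_lstm);
  C.H1d = C.H1 % C.mask1;

  mat Hf2 = lstm_forward(W2f, U2f, b2f, C.H1d, true, C.l2f);
  mat Hb2 = lstm_forward(W2b, U2b, b2b, C.H1d, false, C.l2b);
  C.H2 = join_cols(Hf2, Hb2);
  C.mask2 = make_mask(C.H2.n_rows, n, drop_lstm);
  C.H2d = C.H2 % C.mask2;

  C.T = tanh(Ws1 * C.H2d);
  mat S = Ws2 * C.T;
  C.A.set_size(S.n_rows, n);
  for (uword k = 0; k < S.n_rows; ++k) {
    rowvec s = S.row(k);
    s -= s.max();
    rowvec e = exp(s);
    C.A.row(k) = e / accu(e);
  }
  C.M = C.A * C.H2d.t();
  C.m_flat = vectorise(C.M);
  C.mask3 = make_mask(C.m_flat.n_elem, 1, drop_dense).col(0);
  C.m_drop = C.m_flat % C.mask3;
  C.z = Wd * C.m_drop + bd;
  C.p = 1.0 / (1.0 + exp(-C.z));

  C.org.set_size(n_org);
  C.org_arg.set_size(n_org);
  for (int cidx = 0; cidx < n_org; ++cidx) {
    vec col = C.p.subvec(8 * cidx, 8 * cidx + 7);
    C.org_arg(cidx) = 8 * cidx + col.index_max();
    C.org(cidx) = col.max();
  }
}

static double bce(double p, double y) {
  const double eps = 1e-12;
  p = std::min(std::max(p, eps), 1.0 - eps);
  return -(y * std::log(p) + (1.0 - y) * std::log(1.0 - p));
}

// Loss (and optionally gradients) for one sample given its cache.
static double loss_and_backward(const std::vector<mat>& P, FwdCache& C,
                                const vec& tmat, const vec& torg,
                                bool lv1_only, const vec& cell_mask,
                                double lambda, int n_org,
                                std::vector<mat>* G) {
  const mat &Ws1 = P[12], &Ws2 = P[13], &Wd = P[14];
  const uword D = C.p.n_elem;
  const double n_cells = accu(cell_mask);

  double L1 = 0.0, L2 = 0.0;
  if (!lv1_only) {
    for (uword j = 0; j < D; ++j)
      if (cell_mask(j) > 0) L1 += bce(C.p(j), tmat(j));
    L1 /= n_cells;
  }
  for (int cidx = 0; cidx < n_org; ++cidx) L2 += bce(C.org(cidx), torg(cidx));
  L2 /= n_org;

  mat AAtI = C.A * C.A.t();
  AAtI.diag() -= 1.0;
  double pen = accu(square(AAtI));
  double loss = (lv1_only ? 0.0 : L1) + L2 + lambda * pen;
  if (G == nullptr) return loss;

  // ---- backward ----
  vec dz(D, fill::zeros);
  if (!lv1_only) dz = (C.p - tmat) % cell_mask / n_cells;
  for (int cidx = 0; cidx < n_org; ++cidx)
    dz(C.org_arg(cidx)) += (C.org(cidx) - torg(cidx)) / n_org;

  (*G)[14] += dz * C.m_drop.t();
  (*G)[15] += dz;
  vec dm = (Wd.t() * dz) % C.mask3;
  mat dM(dm.memptr(), C.M.n_rows, C.M.n_cols);

  mat dA = dM * C.H2d;                         // r x n
  dA += lambda * 4.0 * (AAtI * C.A);
  mat dH2d = dM.t() * C.A;                     // 2u x n  (from M = A H^T path)

  mat dS(dA.n_rows, dA.n_cols);
  for (uword k = 0; k < dA.n_rows; ++k) {
    double s = dot(dA.row(k), C.A.row(k));
    dS.row(k) = C.A.row(k) % (dA.row(k) - s);
  }
  (*G)[13] += dS * C.T.t();
  mat dT = Ws2.t() * dS;
  mat dPre = dT % (1.0 - square(C.T));
  (*G)[12] += dPre * C.H2d.t();
  dH2d += Ws1.t() * dPre;

  mat dH2 = dH2d % C.mask2;
  const uword u2 = C.H2.n_rows / 2;
  mat dHf2 = dH2.rows(0, u2 - 1), dHb2 = dH2.rows(u2, 2 * u2 - 1);
  vec db2f = (*G)[8].col(0), db2b = (*G)[11].col(0);
  mat dH1d = lstm_backward(P[6], P[7], C.H1d, C.l2f, dHf2,
                           (*G)[6], (*G)[7], db2f);
  dH1d += lstm_backward(P[9], P[10], C.H1d, C.l2b, dHb2,
                        (*G)[9], (*G)[10], db2b);
  (*G)[8].col(0) = db2f; (*G)[11].col(0) = db2b;

  mat dH1 = dH1d % C.mask1;
  const uword u1 = C.H1.n_rows / 2;
  mat dHf1 = dH1.rows(0, u1 - 1), dHb1 = dH1.rows(u1, 2 * u1 - 1);
  vec db1f = (*G)[2].col(0), db1b = (*G)[5].col(0);
  lstm_backward(P[0], P[1], C.X, C.l1f, dHf1, (*G)[0], (*G)[1], db1f);
  lstm_backward(P[3], P[4], C.X, C.l1b, dHb1, (*G)[3], (*G)[4], db1b);
  (*G)[2].col(0) = db1f; (*G)[5].col(0) = db1b;
  return loss;
}

// [[Rcpp::export]]
List cpp_forward(List params, const arma::mat& X, int n_org) {
  std::vector<mat> P = params_from_list(params);
  FwdCache C;
  std::mt19937_64 rng(0);
  forward_full(P, X, n_org, false, 0.0, 0.0, rng, C);
  return List::create(Named("scores") = C.p, Named("org") = C.org,
                      Named("A") = C.A, Named("M") = C.M,
                      Named("H") = C.H2.t());
}

// [[Rcpp::export]]
double cpp_sample_loss(List params, const arma::mat& X, const arma::vec& tmat,
                       const arma::vec& torg, bool lv1_only,
                       const arma::vec& cell_mask, double lambda, int n_org) {
  std::vector<mat> P = params_from_list(params);
  FwdCache C;
  std::mt19937_64 rng(0);
  forward_full(P, X, n_org, false, 0.0, 0.0, rng, C);
  return loss_and_backward(P, C, tmat, torg, lv1_only, cell_mask, lambda,
                           n_org, nullptr);
}

// Per-sample analytic gradients (no dropout); used by the finite-difference
// checks in the test suite.
// [[Rcpp::export]]
List cpp_grad(List params, const arma::mat& X, const arma::vec& tmat,
              const arma::vec& torg, bool lv1_only,
              const arma::vec& cell_mask, double lambda, int n_org) {
  std::vector<mat> P = params_from_list(params);
  std::vector<mat> G(N_PARAMS);
  for (int i = 0; i < N_PARAMS; ++i)
    G[i] = mat(P[i].n_rows, P[i].n_cols, fill::zeros);
  FwdCache C;
  std::mt19937_64 rng(0);
  forward_full(P, X, n_org, false, 0.0, 0.0, rng, C);
  double loss = loss_and_backward(P, C, tmat, torg, lv1_only, cell_mask,
                                  lambda, n_org, &G);
  return List::create(Named("loss") = loss, Named("grads") = params_to_list(G));
}

// One epoch of minibatch Adam over the supplied samples, in the supplied
// order.  Returns updated parameters, Adam state and the mean sample loss.
// [[Rcpp::export]]
List cpp_train_epoch(List params, List adam_m, List adam_v, int adam_t,
                     List xs, List tmats, List torgs,
                     Rcpp::LogicalVector lv1_only, const arma::vec& cell_mask,
                     int n_org, double lambda, double lr,
                     double beta1, double beta2, double eps,
                     double drop_lstm, double drop_dense,
                     int batch_size, double grad_clip, double weight_decay,
                     Rcpp::IntegerVector order, int seed) {
  std::vector<mat> P = params_from_list(params);
  std::vector<mat> M = params_from_list(adam_m);
  std::vector<mat> V = params_from_list(adam_v);
  std::vector<mat> G(N_PARAMS);
  const int ns = order.size();
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  double total_loss = 0.0;
  int in_batch = 0;

  auto zero_grads = [&]() {
    for (int i = 0; i < N_PARAMS; ++i) G[i] = mat(P[i].n_rows, P[i].n_cols, fill::zeros);
  };
  auto adam_step = [&]() {
    if (in_batch == 0) return;
    adam_t += 1;
    double bc1 = 1.0 - std::pow(beta1, adam_t);
    double bc2 = 1.0 - std::pow(beta2, adam_t);
    double gnorm2 = 0.0;
    for (int i = 0; i < N_PARAMS; ++i)
      gnorm2 += accu(square(G[i] / in_batch));
    double scale = 1.0;
    if (grad_clip > 0 && std::sqrt(gnorm2) > grad_clip)
      scale = grad_clip / std::sqrt(gnorm2);
    for (int i = 0; i < N_PARAMS; ++i) {
      mat g = scale * G[i] / in_batch;
      M[i] = beta1 * M[i] + (1.0 - beta1) * g;
      V[i] = beta2 * V[i] + (1.0 - beta2) * square(g);
      P[i] -= lr * (M[i] / bc1) / (sqrt(V[i] / bc2) + eps);
      // decoupled weight decay on weight matrices (biases exempt)
      if (weight_decay > 0 && i != 2 && i != 5 && i != 8 && i != 11 && i != 15)
        P[i] -= lr * weight_decay * P[i];
    }
    in_batch = 0;
    zero_grads();
  };

  zero_grads();
  FwdCache C;
  for (int k = 0; k < ns; ++k) {
    int idx = order[k] - 1;  // 1-based from R
    const mat X = Rcpp::as<mat>(xs[idx]);
    const vec tmat = Rcpp::as<vec>(tmats[idx]);
    const vec torg = Rcpp::as<vec>(torgs[idx]);
    forward_full(P, X, n_org, true, drop_lstm, drop_dense, rng, C);
    total_loss += loss_and_backward(P, C, tmat, torg, lv1_only[idx],
                                    cell_mask, lambda, n_org, &G);
    in_batch += 1;
    if (in_batch == batch_size) adam_step();
  }
  adam_step();

  return List::create(Named("params") = params_to_list(P),
                      Named("adam_m") = params_to_list(M),
                      Named("adam_v") = params_to_list(V),
                      Named("adam_t") = adam_t,
                      Named("mean_loss") = total_loss / std::max(ns, 1));
}
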