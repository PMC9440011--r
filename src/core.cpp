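// Forward simulation and backpropagation-through-time for the three-module
// (upstream -> PMd -> M1) leaky firing-rate network, plus the Adam training
// loop. Templated on the element type so training can run in single
// precision while all evaluation paths stay double.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// parameter-group order used throughout (must match R side):
// 0 W_up, 1 W_pmd, 2 W_m1, 3 W_up_pmd, 4 W_pmd_m1,
// 5 W_in_up, 6 W_in_pmd, 7 W_out, 8 b_out
static const int N_GROUPS = 9;

template <typename eT>
struct Net {
  Mat<eT> W[8];
  Col<eT> b_out;
  eT k;  // dt / tau
  int N;
};

template <typename eT>
static Net<eT> net_from_list(const Rcpp::List& p) {
  Net<eT> net;
  const char* nm[8] = {"W_up", "W_pmd", "W_m1", "W_up_pmd", "W_pmd_m1",
                       "W_in_up", "W_in_pmd", "W_out"};
  for (int i = 0; i < 8; ++i)
    net.W[i] = conv_to<Mat<eT>>::from(Rcpp::as<mat>(p[nm[i]]));
  net.b_out = conv_to<Col<eT>>::from(Rcpp::as<vec>(p["b_out"]));
  double dt = Rcpp::as<double>(p["dt"]);
  double tau = Rcpp::as<double>(p["tau"]);
  net.k = static_cast<eT>(dt / tau);
  net.N = net.W[0].n_rows;
  return net;
}

template <typename eT>
struct FBWork {
  Cube<eT> R1, R2, R3;   // rates, slice t = tanh(x^(t)), slice 0 = rates at x0 (zero)
  Cube<eT> out;          // 2 x B x T, slice t-1 = output at step t
  double loss, err, wreg, rreg;
  Mat<eT> g[8];
  Col<eT> g_b;
};

// One forward pass (and optionally backward) over a batch.
// S: 3 x B x T (slice t-1 = input at step t), Y: 2 x B x T targets.
template <typename eT>
static void forward_backward(const Net<eT>& net, const Cube<eT>& S,
                             const Cube<eT>& Y, double alpha, double beta_r,
                             int loss_start, bool want_grads, FBWork<eT>& w) {
  const int N = net.N, B = S.n_cols, T = S.n_slices;
  const eT k = net.k, omk = eT(1) - k;
  const Mat<eT>& W_up = net.W[0];
  const Mat<eT>& W_pmd = net.W[1];
  const Mat<eT>& W_m1 = net.W[2];
  const Mat<eT>& W_up_pmd = net.W[3];
  const Mat<eT>& W_pmd_m1 = net.W[4];
  const Mat<eT>& W_in_up = net.W[5];
  const Mat<eT>& W_in_pmd = net.W[6];
  const Mat<eT>& W_out = net.W[7];

  w.R1.zeros(N, B, T + 1);
  w.R2.zeros(N, B, T + 1);
  w.R3.zeros(N, B, T + 1);
  w.out.set_size(2, B, T);

  Mat<eT> x1(N, B, fill::zeros), x2(N, B, fill::zeros), x3(N, B, fill::zeros);
  for (int t = 1; t <= T; ++t) {
    const Mat<eT>& r1p = w.R1.slice(t - 1);
    const Mat<eT>& r2p = w.R2.slice(t - 1);
    const Mat<eT>& r3p = w.R3.slice(t - 1);
    const Mat<eT>& s = S.slice(t - 1);
    x1 = omk * x1 + k * (W_up * r1p + W_in_up * s);
    x2 = omk * x2 + k * (W_pmd * r2p + W_up_pmd * r1p + W_in_pmd * s);
    x3 = omk * x3 + k * (W_m1 * r3p + W_pmd_m1 * r2p);
    w.R1.slice(t) = tanh(x1);
    w.R2.slice(t) = tanh(x2);
    w.R3.slice(t) = tanh(x3);
    w.out.slice(t - 1) = W_out * w.R3.slice(t);
    w.out.slice(t - 1).each_col() += net.b_out;
  }

  // loss components (accumulated in double)
  const double err_norm = double(B) * (T - loss_start) * 2.0;
  double err = 0.0;
  for (int t = loss_start + 1; t <= T; ++t) {
    err += accu(conv_to<mat>::from(
        square(w.out.slice(t - 1) - Y.slice(t - 1))));
  }
  err /= err_norm;
  double wreg = 0.0;
  for (int i = 0; i < 8; ++i) wreg += norm(net.W[i], "fro");
  wreg *= alpha;
  double rr = 0.0;
  for (int t = 1; t <= T; ++t) {
    rr += accu(conv_to<mat>::from(square(w.R1.slice(t)))) +
          accu(conv_to<mat>::from(square(w.R2.slice(t)))) +
          accu(conv_to<mat>::from(square(w.R3.slice(t))));
  }
  double rreg = beta_r * rr / (double(B) * T * N);
  w.err = err;
  w.wreg = wreg;
  w.rreg = rreg;
  w.loss = err + wreg + rreg;
  if (!want_grads) return;

  // backward pass
  const eT cr = eT(2.0 * beta_r / (double(B) * T * N));
  const eT ce = eT(1.0 / (double(B) * (T - loss_start)));
  Cube<eT> L1(N, B, T), L2(N, B, T), L3(N, B, T);  // slice t-1 = lambda^(t)
  Cube<eT> GO(2, B, T, fill::zeros);               // d err / d out
  Mat<eT> l1(N, B, fill::zeros), l2(N, B, fill::zeros), l3(N, B, fill::zeros);
  for (int t = T; t >= 1; --t) {
    Mat<eT> g3 = cr * w.R3.slice(t) + k * (W_m1.t() * l3);
    if (t > loss_start) {
      GO.slice(t - 1) = ce * (w.out.slice(t - 1) - Y.slice(t - 1));
      g3 += W_out.t() * GO.slice(t - 1);
    }
    Mat<eT> g2 =
        cr * w.R2.slice(t) + k * (W_pmd.t() * l2) + k * (W_pmd_m1.t() * l3);
    Mat<eT> g1 =
        cr * w.R1.slice(t) + k * (W_up.t() * l1) + k * (W_up_pmd.t() * l2);
    l3 = omk * l3 + (eT(1) - square(w.R3.slice(t))) % g3;
    l2 = omk * l2 + (eT(1) - square(w.R2.slice(t))) % g2;
    l1 = omk * l1 + (eT(1) - square(w.R1.slice(t))) % g1;
    L1.slice(t - 1) = l1;
    L2.slice(t - 1) = l2;
    L3.slice(t - 1) = l3;
  }

  // weight gradients as single large GEMMs over the flattened time axis
  const uword BT = uword(B) * T;
  Mat<eT> L1m(L1.memptr(), N, BT, false), L2m(L2.memptr(), N, BT, false),
      L3m(L3.memptr(), N, BT, false);
  Mat<eT> R1m(w.R1.memptr(), N, BT, false),   // rates r^(0..T-1)
      R2m(w.R2.memptr(), N, BT, false), R3m(w.R3.memptr(), N, BT, false);
  Mat<eT> R3s(w.R3.memptr() + uword(N) * B, N, BT, false);  // r3^(1..T)
  Mat<eT> Sm(const_cast<eT*>(S.memptr()), 3, BT, false);
  Mat<eT> GOm(GO.memptr(), 2, BT, false);
  w.g[0] = k * (L1m * R1m.t());
  w.g[1] = k * (L2m * R2m.t());
  w.g[2] = k * (L3m * R3m.t());
  w.g[3] = k * (L2m * R1m.t());
  w.g[4] = k * (L3m * R2m.t());
  w.g[5] = k * (L1m * Sm.t());
  w.g[6] = k * (L2m * Sm.t());
  w.g[7] = GOm * R3s.t();
  w.g_b = sum(GOm, 1);
  // gradient of the (unsquared) Frobenius-norm regularizer
  for (int i = 0; i < 8; ++i) {
    double nrm = norm(net.W[i], "fro");
    if (nrm > 0) w.g[i] += eT(alpha / nrm) * net.W[i];
  }
}

// gather a batch of trials into time-sliced cubes
template <typename eT>
static void gather_batch(const Cube<eT>& stim, const Cube<eT>& targ,
                         const Rcpp::IntegerMatrix& idx, int u, Cube<eT>& S,
                         Cube<eT>& Y) {
  const int B = idx.ncol(), T = stim.n_cols;
  for (int b = 0; b < B; ++b) {
    int j = idx(u, b) - 1;
    for (int t = 0; t < T; ++t) {
      S.slice(t).col(b) = stim.slice(j).col(t);
      Y.slice(t).col(b) = targ.slice(j).col(t);
    }
  }
}

template <typename eT>
static Rcpp::List train_impl(const Rcpp::List& params, const cube& stim,
                             const cube& targ,
                             const Rcpp::IntegerMatrix& batch_idx,
                             const Rcpp::LogicalVector& mask, double lr,
                             double beta1, double beta2, double eps,
                             double clipnorm, double alpha, double beta_r,
                             int loss_start) {
  Net<eT> net = net_from_list<eT>(params);
  const int n_updates = batch_idx.nrow(), B = batch_idx.ncol();
  const int T = stim.n_cols;
  Cube<eT> stimE = conv_to<Cube<eT>>::from(stim);
  Cube<eT> targE = conv_to<Cube<eT>>::from(targ);

  // Adam state for masked groups (b_out handled as a 1-column matrix)
  Mat<eT> m[N_GROUPS], v[N_GROUPS];
  for (int i = 0; i < 8; ++i)
    if (mask[i]) {
      m[i].zeros(net.W[i].n_rows, net.W[i].n_cols);
      v[i].zeros(net.W[i].n_rows, net.W[i].n_cols);
    }
  Col<eT> mb, vb;
  if (mask[8]) {
    mb.zeros(net.b_out.n_elem);
    vb.zeros(net.b_out.n_elem);
  }

  Rcpp::NumericVector loss_hist(n_updates), err_hist(n_updates),
      rmse_hist(n_updates);
  Cube<eT> S(3, B, T), Y(2, B, T);
  FBWork<eT> w;
  double b1t = 1.0, b2t = 1.0;
  for (int u = 0; u < n_updates; ++u) {
    gather_batch(stimE, targE, batch_idx, u, S, Y);
    forward_backward(net, S, Y, alpha, beta_r, loss_start, true, w);
    if (!std::isfinite(w.loss))
      Rcpp::stop("training failure: non-finite loss at update %d", u + 1);
    loss_hist[u] = w.loss;
    err_hist[u] = w.err;
    rmse_hist[u] = std::sqrt(w.err);

    // global gradient-norm clipping over the trainable groups only
    double gn2 = 0.0;
    for (int i = 0; i < 8; ++i)
      if (mask[i]) gn2 += accu(conv_to<mat>::from(square(w.g[i])));
    if (mask[8]) gn2 += accu(conv_to<vec>::from(square(w.g_b)));
    double gn = std::sqrt(gn2);
    eT cf = eT(gn > clipnorm ? clipnorm / gn : 1.0);

    b1t *= beta1;
    b2t *= beta2;
    const eT c1 = eT(1.0 / (1.0 - b1t)), c2 = eT(1.0 / (1.0 - b2t));
    for (int i = 0; i < 8; ++i) {
      if (!mask[i]) continue;
      Mat<eT> gc = cf * w.g[i];
      m[i] = eT(beta1) * m[i] + eT(1.0 - beta1) * gc;
      v[i] = eT(beta2) * v[i] + eT(1.0 - beta2) * square(gc);
      net.W[i] -= eT(lr) * (c1 * m[i]) / (sqrt(c2 * v[i]) + eT(eps));
    }
    if (mask[8]) {
      Col<eT> gc = cf * w.g_b;
      mb = eT(beta1) * mb + eT(1.0 - beta1) * gc;
      vb = eT(beta2) * vb + eT(1.0 - beta2) * square(gc);
      net.b_out -= eT(lr) * (c1 * mb) / (sqrt(c2 * vb) + eT(eps));
    }
    if (u % 20 == 0) Rcpp::checkUserInterrupt();
  }

  const char* nm[8] = {"W_up", "W_pmd", "W_m1", "W_up_pmd", "W_pmd_m1",
                       "W_in_up", "W_in_pmd", "W_out"};
  Rcpp::List out;
  for (int i = 0; i < 8; ++i) out[nm[i]] = Rcpp::wrap(conv_to<mat>::from(net.W[i]));
  out["b_out"] = Rcpp::wrap(conv_to<vec>::from(net.b_out));
  return Rcpp::List::create(Rcpp::Named("params") = out,
                            Rcpp::Named("loss_history") = loss_hist,
                            Rcpp::Named("error_history") = err_hist,
                            Rcpp::Named("rmse_history") = rmse_hist);
}

// [[Rcpp::export(name = ".train_cpp")]]
Rcpp::List train_cpp(Rcpp::List params, arma::cube stim, arma::cube targ,
                     Rcpp::IntegerMatrix batch_idx, Rcpp::LogicalVector mask,
                     double lr, double beta1, double beta2, double eps,
                     double clipnorm, double alpha, double beta_r,
                     int loss_start, std::string precision) {
  if (mask.size() != N_GROUPS) Rcpp::stop("mask must have 9 entries");
  if (precision == "single")
    return train_impl<float>(params, stim, targ, batch_idx, mask, lr, beta1,
                             beta2, eps, clipnorm, alpha, beta_r, loss_start);
  return train_impl<double>(params, stim, targ, batch_idx, mask, lr, beta1,
                            beta2, eps, clipnorm, alpha, beta_r, loss_start);
}

// Single-trial forward simulation in double precision.
// stim: 3 x T; x0: optional list of three N-vectors.
// [[Rcpp::export(name = ".sim_trial_cpp")]]
Rcpp::List sim_trial_cpp(Rcpp::List params, arma::mat stim,
                         Rcpp::Nullable<Rcpp::List> x0 = R_NilValue) {
  Net<double> net = net_from_list<double>(params);
  const int N = net.N, T = stim.n_cols;
  const double k = net.k, omk = 1.0 - k;
  vec x1(N, fill::zeros), x2(N, fill::zeros), x3(N, fill::zeros);
  if (x0.isNotNull()) {
    Rcpp::List x0l(x0);
    x1 = Rcpp::as<vec>(x0l["up"]);
    x2 = Rcpp::as<vec>(x0l["pmd"]);
    x3 = Rcpp::as<vec>(x0l["m1"]);
  }
  mat X1(N, T), X2(N, T), X3(N, T), OUT(2, T);
  for (int t = 0; t < T; ++t) {
    vec s = stim.col(t);
    vec r1 = tanh(x1), r2 = tanh(x2), r3 = tanh(x3);
    x1 = omk * x1 + k * (net.W[0] * r1 + net.W[5] * s);
    x2 = omk * x2 + k * (net.W[1] * r2 + net.W[3] * r1 + net.W[6] * s);
    x3 = omk * x3 + k * (net.W[2] * r3 + net.W[4] * r2);
    if (!x1.is_finite() || !x2.is_finite() || !x3.is_finite())
      Rcpp::stop("numerical instability: non-finite state at step %d", t + 1);
    X1.col(t) = x1;
    X2.col(t) = x2;
    X3.col(t) = x3;
    OUT.col(t) = net.W[7] * tanh(x3) + net.b_out;
  }
  return Rcpp::List::create(
      Rcpp::Named("x_up") = X1, Rcpp::Named("x_pmd") = X2,
      Rcpp::Named("x_m1") = X3, Rcpp::Named("output") = OUT);
}

// Batched loss + gradients in double precision (testing / inspection).
// stim: 3 x T x B per-trial layout; targ: 2 x T x B.
// [[Rcpp::export(name = ".loss_grad_cpp")]]
Rcpp::List loss_grad_cpp(Rcpp::List params, arma::cube stim, arma::cube targ,
                         double alpha, double beta_r, int loss_start) {
  Net<double> net = net_from_list<double>(params);
  const int B = stim.n_slices, T = stim.n_cols;
  Cube<double> S(3, B, T), Y(2, B, T);
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < T; ++t) {
      S.slice(t).col(b) = stim.slice(b).col(t);
      Y.slice(t).col(b) = targ.slice(b).col(t);
    }
  FBWork<double> w;
  forward_backward(net, S, Y, alpha, beta_r, loss_start, true, w);
  const char* nm[8] = {"W_up", "W_pmd", "W_m1", "W_up_pmd", "W_pmd_m1",
                       "W_in_up", "W_in_pmd", "W_out"};
  Rcpp::List g;
  for (int i = 0; i < 8; ++i) g[nm[i]] = Rcpp::wrap(w.g[i]);
  g["b_out"] = Rcpp::wrap(w.g_b);
  // outputs back to per-trial layout 2 x T x B
  cube outp(2, T, B);
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < T; ++t) outp.slice(b).col(t) = w.out.slice(t).col(b);
  return Rcpp::List::create(
      Rcpp::Named("loss") = w.loss, Rcpp::Named("error") = w.err,
      Rcpp::Named("weights") = w.wreg, Rcpp::Named("rates") = w.rreg,
      Rcpp::Named("gradients") = g, Rcpp::Named("output") = outp);
}
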