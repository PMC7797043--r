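// Multitask 1-D convolutional network over one-hot DNA.
//
// Layout conventions (all column-major, matching R):
//   batch tensor  : cube (channels, length, batch)
//   conv weights  : mat (n_filters, channels * width); the column for
//                   offset k within the window and channel c is k*C + c
//   dense weights : mat (units_out, units_in)
// Each conv layer is conv -> (per-filter batch norm) -> ReLU -> max-pool.
// The convolution is computed as im2col + GEMM so BLAS does the work.
// All randomness (init, dropout masks, shuffling) is generated in R and
// passed in, keeping this unit fully deterministic.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using Rcpp::List;
using Rcpp::IntegerVector;
using Rcpp::Named;

static const double BN_EPS = 1e-5;

static mat pad_slice(const mat& x, int pad) {
  if (pad <= 0) return x;
  const int left = pad / 2, right = pad - left;
  mat xp(x.n_rows, x.n_cols + left + right, fill::zeros);
  xp.cols(left, left + x.n_cols - 1) = x;
  return xp;
}

static mat im2col(const mat& xp, int K) {
  const int C = xp.n_rows;
  const int Lout = (int)xp.n_cols - K + 1;
  if (Lout <= 0) Rcpp::stop("convolution window wider than (padded) input");
  mat out(C * K, Lout);
  for (int k = 0; k < K; ++k)
    out.rows(k * C, k * C + C - 1) = xp.cols(k, k + Lout - 1);
  return out;
}

static void col2im_add(mat& xp, const mat& dcol, int K) {
  const int C = xp.n_rows;
  const int Lout = dcol.n_cols;
  for (int k = 0; k < K; ++k)
    xp.cols(k, k + Lout - 1) += dcol.rows(k * C, k * C + C - 1);
}

// max-pool width = stride = p, trailing remainder dropped
static void maxpool(const cube& A, int p, cube& out, ucube& argmax) {
  const int F = A.n_rows, L = A.n_cols, N = A.n_slices;
  const int Lp = L / p;
  if (Lp <= 0) Rcpp::stop("pool width reduces length to zero");
  out.set_size(F, Lp, N);
  argmax.set_size(F, Lp, N);
  for (int n = 0; n < N; ++n)
    for (int j = 0; j < Lp; ++j) {
      for (int f = 0; f < F; ++f) {
        double best = A(f, j * p, n);
        int bi = j * p;
        for (int k = 1; k < p; ++k) {
          const double v = A(f, j * p + k, n);
          if (v > best) { best = v; bi = j * p + k; }
        }
        out(f, j, n) = best;
        argmax(f, j, n) = bi;
      }
    }
}

struct ConvCache {
  cube cols;   // (C*K, Lout, N)
  cube Z;      // pre-activation, post-BN when bn on (F, Lout, N)
  cube A;      // post-activation (stored only for the exp activation)
  cube Zhat;   // normalized pre-scale activations (bn only)
  vec sigma;   // per-filter batch std (bn only)
  ucube amax;  // pool argmax
  ucube orient; // 1 where the reverse-complement orientation won (rc conv)
  bool exp_act = false;
  int in_len;
  int in_ch;
};

// first-layer activation: saturating exponential (tail amplifier that makes
// rare strong motif alignments dominate pooling) or ReLU
static cube exp_activation(const cube& Z) {
  return exp(clamp(Z, -50.0, 20.0));
}

// reverse-complement weight map for a first-layer filter matrix over one-hot
// DNA: reverse the position order and swap A<->T, C<->G (row order ACGT)
static mat rc_filter(const mat& W, int K) {
  mat out(size(W));
  for (uword f = 0; f < W.n_rows; ++f)
    for (int k = 0; k < K; ++k)
      for (int b = 0; b < 4; ++b)
        out(f, k * 4 + b) = W(f, (K - 1 - k) * 4 + (3 - b));
  return out;
}

// forward through conv stack; caches kept only when `train`.
// bn_*: per-layer per-filter vectors. In training mode batch statistics are
// computed here and written into batch_mean/batch_var (per layer); in eval
// mode running statistics are used.
static cube conv_forward(const cube& X, const List& conv_W, const List& conv_b,
                         const IntegerVector& pool_w, const IntegerVector& pad_w,
                         bool batch_norm, const List& bn_gamma,
                         const List& bn_beta, const List& bn_mean,
                         const List& bn_var, bool rc_conv, bool exp_act,
                         bool train,
                         std::vector<ConvCache>& caches,
                         std::vector<vec>* batch_mean,
                         std::vector<vec>* batch_var,
                         int nullify_filter = 0, double nullify_value = 0.0) {
  cube cur = X;
  const int nconv = conv_W.size();
  for (int l = 0; l < nconv; ++l) {
    const mat W = conv_W[l];
    const vec b = Rcpp::as<vec>(conv_b[l]);
    const int K = W.n_cols / cur.n_rows;
    if ((int)W.n_cols != K * (int)cur.n_rows)
      Rcpp::stop("conv weight width not a multiple of input channels");
    const int F = W.n_rows, N = cur.n_slices;
    const int Lout = (int)cur.n_cols + pad_w[l] - K + 1;
    if (Lout <= 0) Rcpp::stop("conv output length <= 0");
    cube Z(F, Lout, N);
    cube cols;
    ConvCache cc;
    const bool rc_here = rc_conv && l == 0 && cur.n_rows == 4;
    mat Wrc;
    if (rc_here) {
      Wrc = rc_filter(W, K);
      cc.orient.set_size(F, Lout, N);
    }
    if (train) cols.set_size(K * cur.n_rows, Lout, N);
    for (int n = 0; n < N; ++n) {
      mat col = im2col(pad_slice(cur.slice(n), pad_w[l]), K);
      if (rc_here) {
        // strand-tied filter: per position keep the better orientation
        mat Zf = W * col;
        mat Zr = Wrc * col;
        umat o = Zr > Zf;
        Z.slice(n) = max(Zf, Zr);
        cc.orient.slice(n) = o;
      } else {
        Z.slice(n) = W * col;
      }
      Z.slice(n).each_col() += b;
      if (train) cols.slice(n) = col;
    }
    if (batch_norm) {
      const vec gamma = Rcpp::as<vec>(bn_gamma[l]);
      const vec beta = Rcpp::as<vec>(bn_beta[l]);
      vec mu(F), s2(F);
      if (train) {
        const double m = (double)Lout * (double)N;
        for (int f = 0; f < F; ++f) {
          double acc = 0.0;
          for (int n = 0; n < N; ++n) acc += accu(Z.slice(n).row(f));
          mu[f] = acc / m;
          acc = 0.0;
          for (int n = 0; n < N; ++n)
            acc += accu(square(Z.slice(n).row(f) - mu[f]));
          s2[f] = acc / m;
        }
        if (batch_mean) batch_mean->push_back(mu);
        if (batch_var) batch_var->push_back(s2);
      } else {
        mu = Rcpp::as<vec>(bn_mean[l]);
        s2 = Rcpp::as<vec>(bn_var[l]);
      }
      const vec sigma = sqrt(s2 + BN_EPS);
      cube Zhat(F, Lout, N);
      for (int n = 0; n < N; ++n)
        for (int f = 0; f < F; ++f)
          Zhat.slice(n).row(f) = (Z.slice(n).row(f) - mu[f]) / sigma[f];
      for (int n = 0; n < N; ++n)
        for (int f = 0; f < F; ++f)
          Z.slice(n).row(f) = gamma[f] * Zhat.slice(n).row(f) + beta[f];
      if (train) {
        cc.Zhat = std::move(Zhat);
        cc.sigma = sigma;
      }
    }
    const bool exp_here = exp_act && l == 0;
    cube A = exp_here ? exp_activation(Z)
                      : clamp(Z, 0.0, datum::inf);  // ReLU
    if (l == 0 && nullify_filter > 0) {
      // filter ablation: the nullified filter's output map is replaced by a
      // constant (its mean over the evaluation set), blocking its signal
      A.row(nullify_filter - 1).fill(nullify_value);
    }
    cube pooled; ucube amax;
    maxpool(A, pool_w[l], pooled, amax);
    if (train) {
      cc.cols = std::move(cols);
      cc.Z = std::move(Z);
      cc.exp_act = exp_here;
      if (exp_here) cc.A = A;
      cc.amax = std::move(amax);
      cc.in_len = cur.n_cols;
      cc.in_ch = cur.n_rows;
      caches.push_back(std::move(cc));
    }
    cur = std::move(pooled);
  }
  return cur;
}

static mat flatten_cube(const cube& A) {
  mat H(A.n_rows * A.n_cols, A.n_slices);
  for (uword n = 0; n < A.n_slices; ++n)
    H.col(n) = vectorise(A.slice(n));
  return H;
}

// [[Rcpp::export]]
arma::mat cpp_predict(List conv_W, List conv_b, IntegerVector pool_w,
                      IntegerVector pad_w, List dense_W, List dense_b,
                      arma::cube X, bool batch_norm, List bn_gamma,
                      List bn_beta, List bn_mean, List bn_var,
                      int nullify_filter = 0, double nullify_value = 0.0,
                      bool global_pool = false, bool rc_conv = false,
                      bool exp_act = false) {
  std::vector<ConvCache> dummy;
  cube pooled = conv_forward(X, conv_W, conv_b, pool_w, pad_w, batch_norm,
                             bn_gamma, bn_beta, bn_mean, bn_var, rc_conv,
                             exp_act, false, dummy,
                             nullptr, nullptr, nullify_filter, nullify_value);
  if (global_pool) {
    cube gp; ucube gpa;
    maxpool(pooled, pooled.n_cols, gp, gpa);
    pooled = std::move(gp);
  }
  mat H = flatten_cube(pooled);
  const int nd = dense_W.size();
  for (int j = 0; j < nd; ++j) {
    const mat W = dense_W[j];
    const vec b = Rcpp::as<vec>(dense_b[j]);
    H = W * H;
    H.each_col() += b;
    if (j < nd - 1) H = clamp(H, 0.0, datum::inf);
  }
  return 1.0 / (1.0 + exp(-H));  // (F_out x N)
}

List cpp_conv1_activations(arma::mat W, arma::vec b, int pad,
                           arma::cube X, bool rc_conv);

// post-BN, post-activation first-layer output maps in evaluation mode
// (running BN statistics), as passed forward by the network
// [[Rcpp::export]]
List cpp_conv1_output(arma::mat W, arma::vec b, int pad, arma::cube X,
                      bool batch_norm, arma::vec gamma, arma::vec beta,
                      arma::vec rmean, arma::vec rvar,
                      bool rc_conv = false, bool exp_act = false) {
  List raw = cpp_conv1_activations(W, b, pad, X, rc_conv);
  cube Z = raw["Z"];
  if (batch_norm) {
    const vec sigma = sqrt(rvar + BN_EPS);
    for (uword n = 0; n < Z.n_slices; ++n)
      for (uword f = 0; f < Z.n_rows; ++f)
        Z.slice(n).row(f) =
            gamma[f] * (Z.slice(n).row(f) - rmean[f]) / sigma[f] + beta[f];
  }
  cube A = exp_act ? exp_activation(Z) : clamp(Z, 0.0, datum::inf);
  return List::create(Named("A") = A, Named("orient") = raw["orient"]);
}

// raw (pre-BN, pre-activation) first-layer filter activations, for PWM
// conversion; with rc_conv the per-position orientation winner is returned
// alongside (0 = forward, 1 = reverse complement)
// [[Rcpp::export]]
List cpp_conv1_activations(arma::mat W, arma::vec b, int pad,
                           arma::cube X, bool rc_conv = false) {
  const int K = W.n_cols / X.n_rows;
  const int Lout = (int)X.n_cols + pad - K + 1;
  cube Z(W.n_rows, Lout, X.n_slices);
  cube orient(W.n_rows, Lout, X.n_slices, fill::zeros);
  mat Wrc;
  if (rc_conv) Wrc = rc_filter(W, K);
  for (uword n = 0; n < X.n_slices; ++n) {
    mat col = im2col(pad_slice(X.slice(n), pad), K);
    if (rc_conv) {
      mat Zf = W * col;
      mat Zr = Wrc * col;
      Z.slice(n) = max(Zf, Zr);
      orient.slice(n) = conv_to<mat>::from(Zr > Zf);
    } else {
      Z.slice(n) = W * col;
    }
    Z.slice(n).each_col() += b;
  }
  return List::create(Named("Z") = Z, Named("orient") = orient);
}

// one minibatch: forward, mean binary cross-entropy, full backprop
// [[Rcpp::export]]
List cpp_train_batch(List conv_W, List conv_b, IntegerVector pool_w,
                     IntegerVector pad_w, List dense_W, List dense_b,
                     arma::cube X, arma::mat Y, List dropmasks,
                     bool batch_norm, List bn_gamma, List bn_beta,
                     bool global_pool = false, bool rc_conv = false,
                     bool exp_act = false) {
  std::vector<ConvCache> caches;
  std::vector<vec> bmeans, bvars;
  List empty;
  cube conv_out = conv_forward(X, conv_W, conv_b, pool_w, pad_w, batch_norm,
                               bn_gamma, bn_beta, empty, empty, rc_conv,
                               exp_act, true, caches, &bmeans, &bvars);
  cube pooled;
  ucube gp_amax;
  if (global_pool) {
    maxpool(conv_out, conv_out.n_cols, pooled, gp_amax);
  } else {
    pooled = conv_out;
  }
  const int nconv = conv_W.size();
  const int nd = dense_W.size();
  const int N = X.n_slices;

  std::vector<mat> Hs;               // inputs to each dense layer
  std::vector<mat> Zds;              // pre-activations
  mat H = flatten_cube(pooled);
  Hs.push_back(H);
  for (int j = 0; j < nd; ++j) {
    const mat W = dense_W[j];
    const vec b = Rcpp::as<vec>(dense_b[j]);
    mat Z = W * H;
    Z.each_col() += b;
    Zds.push_back(Z);
    if (j < nd - 1) {
      H = clamp(Z, 0.0, datum::inf);
      if (dropmasks.size() > j) {
        const mat m = dropmasks[j];
        H %= m;  // inverted-dropout mask (0 or 1/(1-rate))
      }
      Hs.push_back(H);
    }
  }
  mat P = 1.0 / (1.0 + exp(-Zds.back()));
  const double eps = 1e-12;
  mat Pc = clamp(P, eps, 1.0 - eps);
  const double denom = (double)P.n_rows * (double)N;
  const double loss =
      -accu(Y % log(Pc) + (1.0 - Y) % log(1.0 - Pc)) / denom;
  if (!std::isfinite(loss)) Rcpp::stop("non-finite training loss");

  // ---- backward ----
  List dWd(nd), dbd(nd);
  mat dZ = (P - Y) / denom;
  for (int j = nd - 1; j >= 0; --j) {
    const mat W = dense_W[j];
    dWd[j] = mat(dZ * Hs[j].t());
    dbd[j] = vec(sum(dZ, 1));
    if (j > 0) {
      mat dH = W.t() * dZ;
      if (dropmasks.size() > j - 1) {
        const mat m = dropmasks[j - 1];
        dH %= m;
      }
      dZ = dH % (Zds[j - 1] > 0);
    } else {
      dZ = W.t() * dZ;  // gradient wrt flattened conv output
    }
  }

  List dWc(nconv), dbc(nconv), dgamma(nconv), dbeta(nconv);
  List bmean_out(nconv), bvar_out(nconv);
  // unflatten into cube shaped like last pooled output
  cube dcur(pooled.n_rows, pooled.n_cols, N);
  for (int n = 0; n < N; ++n)
    dcur.slice(n) = reshape(dZ.col(n), pooled.n_rows, pooled.n_cols);
  if (global_pool) {
    // route gradient back through the global max to its argmax position
    cube dfull(conv_out.n_rows, conv_out.n_cols, N, fill::zeros);
    for (int n = 0; n < N; ++n)
      for (uword f = 0; f < conv_out.n_rows; ++f)
        dfull(f, gp_amax(f, 0, n), n) += dcur(f, 0, n);
    dcur = std::move(dfull);
  }

  for (int l = nconv - 1; l >= 0; --l) {
    const ConvCache& cc = caches[l];
    const mat W = conv_W[l];
    const int F = W.n_rows;
    const int K = W.n_cols / cc.in_ch;
    const int Lout = cc.Z.n_cols;
    mat dW(size(W), fill::zeros);
    vec db(F, fill::zeros);
    const bool need_dx = (l > 0);
    cube dprev;
    if (need_dx) dprev.zeros(cc.in_ch, cc.in_len, N);

    // un-pool then ReLU gate, collected for the whole batch (BN backward
    // couples all positions and examples of a filter)
    cube dZc(F, Lout, N, fill::zeros);
    for (int n = 0; n < N; ++n) {
      for (int j = 0; j < (int)dcur.n_cols; ++j)
        for (int f = 0; f < F; ++f)
          dZc(f, cc.amax(f, j, n), n) += dcur(f, j, n);
      if (cc.exp_act)
        dZc.slice(n) %= cc.A.slice(n);   // d exp(z)/dz = exp(z)
      else
        dZc.slice(n) %= conv_to<mat>::from(cc.Z.slice(n) > 0);
    }

    if (batch_norm) {
      const vec gamma = Rcpp::as<vec>(bn_gamma[l]);
      const double m = (double)Lout * (double)N;
      vec dg(F), dbta(F);
      // per filter: dZhat = dOut*gamma; dZ = (1/(m*sigma)) *
      //   (m*dZhat - sum(dZhat) - Zhat*sum(dZhat % Zhat))
      for (int f = 0; f < F; ++f) {
        rowvec dout((uword)m), zhat((uword)m);
        uword idx = 0;
        for (int n = 0; n < N; ++n)
          for (int j = 0; j < Lout; ++j, ++idx) {
            dout[idx] = dZc(f, j, n);
            zhat[idx] = cc.Zhat(f, j, n);
          }
        dg[f] = dot(dout, zhat);
        dbta[f] = accu(dout);
        const rowvec dzhat = dout * gamma[f];
        const double s1 = accu(dzhat);
        const double s2 = dot(dzhat, zhat);
        const rowvec dz = (dzhat * m - s1 - zhat * s2) / (m * cc.sigma[f]);
        idx = 0;
        for (int n = 0; n < N; ++n)
          for (int j = 0; j < Lout; ++j, ++idx)
            dZc(f, j, n) = dz[idx];
      }
      dgamma[l] = dg;
      dbeta[l] = dbta;
      bmean_out[l] = bmeans[l];
      bvar_out[l] = bvars[l];
    }

    const bool rc_here = cc.orient.n_elem > 0;
    mat dWrc(size(W), fill::zeros);
    for (int n = 0; n < N; ++n) {
      if (rc_here) {
        mat ofwd = conv_to<mat>::from(cc.orient.slice(n) == 0);
        dW += (dZc.slice(n) % ofwd) * cc.cols.slice(n).t();
        dWrc += (dZc.slice(n) % (1.0 - ofwd)) * cc.cols.slice(n).t();
      } else {
        dW += dZc.slice(n) * cc.cols.slice(n).t();
      }
      db += sum(dZc.slice(n), 1);
      if (need_dx) {
        mat dcol = W.t() * dZc.slice(n);
        mat dxp(cc.in_ch, cc.in_len + pad_w[l], fill::zeros);
        col2im_add(dxp, dcol, K);
        const int left = pad_w[l] / 2;
        dprev.slice(n) = dxp.cols(left, left + cc.in_len - 1);
      }
    }
    if (rc_here) dW += rc_filter(dWrc, K);
    dWc[l] = dW;
    dbc[l] = db;
    if (need_dx) dcur = std::move(dprev);
  }

  return List::create(Named("loss") = loss, Named("conv_dW") = dWc,
                      Named("conv_db") = dbc, Named("dense_dW") = dWd,
                      Named("dense_db") = dbd, Named("bn_dgamma") = dgamma,
                      Named("bn_dbeta") = dbeta,
                      Named("bn_batch_mean") = bmean_out,
                      Named("bn_batch_var") = bvar_out);
}

// mean validation/test loss without gradient bookkeeping
// [[Rcpp::export]]
double cpp_loss(List conv_W, List conv_b, IntegerVector pool_w,
                IntegerVector pad_w, List dense_W, List dense_b,
                arma::cube X, arma::mat Y, bool batch_norm, List bn_gamma,
                List bn_beta, List bn_mean, List bn_var,
                bool global_pool = false, bool rc_conv = false,
                bool exp_act = false) {
  mat P = cpp_predict(conv_W, conv_b, pool_w, pad_w, dense_W, dense_b, X,
                      batch_norm, bn_gamma, bn_beta, bn_mean, bn_var,
                      0, 0.0, global_pool, rc_conv, exp_act);
  const double eps = 1e-12;
  mat Pc = clamp(P, eps, 1.0 - eps);
  return -accu(Y % log(Pc) + (1.0 - Y) % log(1.0 - Pc)) /
         ((double)P.n_rows * (double)P.n_cols);
}
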