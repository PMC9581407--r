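// Compact two-channel CNN for contact-window classification.
//
// Architecture: 3 x [conv 3x3 pad 1 -> batch-norm -> ReLU -> dropout ->
// average pool 2x2 stride 2] -> flatten -> FC -> BN -> ReLU -> FC -> BN ->
// ReLU -> linear -> sigmoid.  Forward/backward use im2col + BLAS gemm via
// Armadillo; all stochastic inputs (dropout uniforms) are supplied by the
// caller so the whole path is reproducible from R's RNG.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double BN_EPS = 1e-5;
static const double PROB_CLAMP = 1e-7;

// im2col for a 3x3 kernel, stride 1, zero padding 1.
// img: (channels, H*W) column-major pixels with q = r + H*c.
// out: (channels*9, H*W); row = krow * C + ch with krow = (dr+1) + 3*(dc+1),
// so each kernel offset is one contiguous C-block per pixel (memcpy-able).
static void im2col3(const arma::mat& img, int H, int W, arma::mat& out) {
  const int C = img.n_rows;
  out.zeros(C * 9, H * W);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      const int q = r + H * c;
      double* oc = out.colptr(q);
      for (int dc = -1; dc <= 1; ++dc) {
        const int cc = c + dc;
        if (cc < 0 || cc >= W) continue;
        for (int dr = -1; dr <= 1; ++dr) {
          const int rr = r + dr;
          if (rr < 0 || rr >= H) continue;
          const int krow = (dr + 1) + 3 * (dc + 1);
          std::memcpy(oc + krow * C, img.colptr(rr + H * cc),
                      C * sizeof(double));
        }
      }
    }
  }
}

// scatter-add counterpart of im2col3
static void col2im3(const arma::mat& cols, int H, int W, arma::mat& img) {
  const int C = img.n_rows;
  img.zeros();
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      const int q = r + H * c;
      const double* sc = cols.colptr(q);
      for (int dc = -1; dc <= 1; ++dc) {
        const int cc = c + dc;
        if (cc < 0 || cc >= W) continue;
        for (int dr = -1; dr <= 1; ++dr) {
          const int rr = r + dr;
          if (rr < 0 || rr >= H) continue;
          const int krow = (dr + 1) + 3 * (dc + 1);
          double* ic = img.colptr(rr + H * cc);
          const double* s = sc + krow * C;
          for (int ch = 0; ch < C; ++ch) ic[ch] += s[ch];
        }
      }
    }
  }
}

// 2x2 average pooling, stride 2, floor semantics (trailing row/col dropped)
static void pool2(const arma::mat& in, int H, int W, arma::mat& out) {
  const int C = in.n_rows;
  const int Ho = H / 2, Wo = W / 2;
  out.set_size(C, Ho * Wo);
  for (int c = 0; c < Wo; ++c) {
    for (int r = 0; r < Ho; ++r) {
      const double* a = in.colptr(2 * r + H * (2 * c));
      const double* b = in.colptr(2 * r + 1 + H * (2 * c));
      const double* d = in.colptr(2 * r + H * (2 * c + 1));
      const double* e = in.colptr(2 * r + 1 + H * (2 * c + 1));
      double* o = out.colptr(r + Ho * c);
      for (int ch = 0; ch < C; ++ch)
        o[ch] = 0.25 * (a[ch] + b[ch] + d[ch] + e[ch]);
    }
  }
}

// backward of pool2: distribute grad/4 to the four source cells
static void unpool2(const arma::mat& g, int H, int W, arma::mat& out) {
  const int C = g.n_rows;
  const int Ho = H / 2, Wo = W / 2;
  out.zeros(C, H * W);
  for (int c = 0; c < Wo; ++c) {
    for (int r = 0; r < Ho; ++r) {
      const double* gp = g.colptr(r + Ho * c);
      double* a = out.colptr(2 * r + H * (2 * c));
      double* b = out.colptr(2 * r + 1 + H * (2 * c));
      double* d = out.colptr(2 * r + H * (2 * c + 1));
      double* e = out.colptr(2 * r + 1 + H * (2 * c + 1));
      for (int ch = 0; ch < C; ++ch) {
        const double v = 0.25 * gp[ch];
        a[ch] += v; b[ch] += v; d[ch] += v; e[ch] += v;
      }
    }
  }
}

struct ConvLayer {
  arma::mat W;            // outc x inc*9
  arma::vec b, gamma, beta, rmean, rvar;
};

struct FcLayer {
  arma::mat W;            // out x in
  arma::vec b, gamma, beta, rmean, rvar;
};

static ConvLayer conv_from_list(const List& l) {
  ConvLayer cl;
  cl.W = as<arma::mat>(l["W"]);
  cl.b = as<arma::vec>(l["b"]);
  cl.gamma = as<arma::vec>(l["gamma"]);
  cl.beta = as<arma::vec>(l["beta"]);
  cl.rmean = as<arma::vec>(l["rmean"]);
  cl.rvar = as<arma::vec>(l["rvar"]);
  return cl;
}

static FcLayer fc_from_list(const List& l) {
  FcLayer fl;
  fl.W = as<arma::mat>(l["W"]);
  fl.b = as<arma::vec>(l["b"]);
  fl.gamma = as<arma::vec>(l["gamma"]);
  fl.beta = as<arma::vec>(l["beta"]);
  fl.rmean = as<arma::vec>(l["rmean"]);
  fl.rvar = as<arma::vec>(l["rvar"]);
  return fl;
}

// reshape (w, w, C, N) R array into cube (C, w*w, N)
static arma::cube array_to_cube(const NumericVector& x, int w, int C, int N) {
  arma::cube A(C, w * w, N);
  const double* px = x.begin();
  const int plane = w * w;
  for (int n = 0; n < N; ++n)
    for (int ch = 0; ch < C; ++ch)
      for (int q = 0; q < plane; ++q)
        A(ch, q, n) = px[q + (std::size_t)plane * ch + (std::size_t)plane * C * n];
  return A;
}

// batch-norm forward over conv cube (per channel across positions x samples)
static void bn_conv_forward_train(const arma::cube& Z, const arma::vec& gamma,
                                  const arma::vec& beta, arma::cube& xhat,
                                  arma::cube& out, arma::vec& mu, arma::vec& var) {
  const int K = Z.n_rows, Q = Z.n_cols, N = Z.n_slices;
  const double M = (double)Q * N;
  mu.zeros(K); var.zeros(K);
  for (int n = 0; n < N; ++n) mu += arma::sum(Z.slice(n), 1);
  mu /= M;
  for (int n = 0; n < N; ++n) {
    arma::mat d = Z.slice(n);
    d.each_col() -= mu;
    var += arma::sum(arma::square(d), 1);
  }
  var /= M;
  arma::vec invstd = 1.0 / arma::sqrt(var + BN_EPS);
  xhat.set_size(K, Q, N); out.set_size(K, Q, N);
  for (int n = 0; n < N; ++n) {
    arma::mat d = Z.slice(n);
    d.each_col() -= mu;
    d.each_col() %= invstd;
    xhat.slice(n) = d;
    d.each_col() %= gamma;
    d.each_col() += beta;
    out.slice(n) = d;
  }
}

// batch-norm backward for conv cube
static void bn_conv_backward(const arma::cube& dy, const arma::cube& xhat,
                             const arma::vec& gamma, const arma::vec& var,
                             arma::cube& dZ, arma::vec& dgamma, arma::vec& dbeta) {
  const int K = dy.n_rows, Q = dy.n_cols, N = dy.n_slices;
  const double M = (double)Q * N;
  dgamma.zeros(K); dbeta.zeros(K);
  for (int n = 0; n < N; ++n) {
    dgamma += arma::sum(dy.slice(n) % xhat.slice(n), 1);
    dbeta += arma::sum(dy.slice(n), 1);
  }
  arma::vec sum_dxhat = dbeta % gamma;
  arma::vec sum_dxhat_xhat = dgamma % gamma;
  arma::vec invstd = 1.0 / arma::sqrt(var + BN_EPS);
  dZ.set_size(K, Q, N);
  for (int n = 0; n < N; ++n) {
    arma::mat dxhat = dy.slice(n);
    dxhat.each_col() %= gamma;
    arma::mat t = dxhat * M;
    t.each_col() -= sum_dxhat;
    t -= xhat.slice(n).each_col() % sum_dxhat_xhat;
    t.each_col() %= (invstd / M);
    dZ.slice(n) = t;
  }
}

// batch-norm forward/backward for FC matrices (rows = units, cols = samples)
static void bn_fc_forward_train(const arma::mat& Z, const arma::vec& gamma,
                                const arma::vec& beta, arma::mat& xhat,
                                arma::mat& out, arma::vec& mu, arma::vec& var) {
  const double M = (double)Z.n_cols;
  mu = arma::mean(Z, 1);
  arma::mat d = Z.each_col() - mu;
  var = arma::sum(arma::square(d), 1) / M;
  arma::vec invstd = 1.0 / arma::sqrt(var + BN_EPS);
  xhat = d.each_col() % invstd;
  out = xhat.each_col() % gamma;
  out.each_col() += beta;
}

static void bn_fc_backward(const arma::mat& dy, const arma::mat& xhat,
                           const arma::vec& gamma, const arma::vec& var,
                           arma::mat& dZ, arma::vec& dgamma, arma::vec& dbeta) {
  const double M = (double)dy.n_cols;
  dgamma = arma::sum(dy % xhat, 1);
  dbeta = arma::sum(dy, 1);
  arma::vec invstd = 1.0 / arma::sqrt(var + BN_EPS);
  arma::mat dxhat = dy.each_col() % gamma;
  arma::mat t = dxhat * M;
  t.each_col() -= arma::sum(dxhat, 1);
  t -= xhat.each_col() % arma::sum(dxhat % xhat, 1);
  t.each_col() %= (invstd / M);
  dZ = t;
}

// Full training forward + backward on one mini-batch.
// x: array (w, w, 2, N); y: labels; dropu: list of 3 uniform vectors
// (length outc_l * H_l^2 * N, H_l the pre-pool spatial size of block l).
// [[Rcpp::export]]
List cpp_cnn_train_batch(List params, NumericVector x, NumericVector y,
                         List dropu, double p_drop) {
  List convs_in = params["conv"];
  List fcs_in = params["fc"];
  List out_in = params["out"];
  ConvLayer cv[3] = {conv_from_list(convs_in[0]), conv_from_list(convs_in[1]),
                     conv_from_list(convs_in[2])};
  FcLayer fc[2] = {fc_from_list(fcs_in[0]), fc_from_list(fcs_in[1])};
  arma::mat Wout = as<arma::mat>(out_in["W"]);
  double bout = as<double>(out_in["b"]);

  IntegerVector dims = x.attr("dim");
  const int w = dims[0], C_in = dims[2], N = dims[3];
  arma::vec yv = as<arma::vec>(y);
  const double dscale = (p_drop > 0.0) ? 1.0 / (1.0 - p_drop) : 1.0;

  int Hin[3];              // pre-pool spatial edge per block
  Hin[0] = w; Hin[1] = w / 2; Hin[2] = w / 4;
  const int Hfl = w / 8;   // spatial edge after the third pool

  // forward through conv blocks
  std::vector<arma::cube> Acts(4);   // inputs to each conv layer (+ flatten)
  std::vector<arma::cube> Xhat(3), Mask(3), BnOut(3), PoolIn(3);
  std::vector<arma::vec> Mu(3), Var(3);
  Acts[0] = array_to_cube(x, w, C_in, N);
  for (int l = 0; l < 3; ++l) {
    const int H = Hin[l], HW = H * H;
    const int Ho = H / 2;
    const int outc = cv[l].W.n_rows;
    arma::cube Z(outc, HW, N);
    arma::mat cols;
    for (int n = 0; n < N; ++n) {
      im2col3(Acts[l].slice(n), H, H, cols);
      Z.slice(n) = cv[l].W * cols;
      Z.slice(n).each_col() += cv[l].b;
    }
    arma::cube xh, bo;
    bn_conv_forward_train(Z, cv[l].gamma, cv[l].beta, xh, bo, Mu[l], Var[l]);
    Xhat[l] = xh; BnOut[l] = bo;
    // ReLU + dropout
    NumericVector uvec = dropu[l];
    const double* pu = uvec.begin();
    arma::cube mask(outc, HW, N);
    arma::cube act(outc, HW, N);
    std::size_t idx = 0;
    for (int n = 0; n < N; ++n)
      for (int q = 0; q < HW; ++q)
        for (int k = 0; k < outc; ++k) {
          double m = (pu[idx++] >= p_drop) ? dscale : 0.0;
          mask(k, q, n) = m;
          double v = bo(k, q, n);
          act(k, q, n) = (v > 0.0) ? v * m : 0.0;
        }
    Mask[l] = mask;
    PoolIn[l] = act;
    arma::cube pooled(outc, Ho * Ho, N);
    arma::mat tmp;
    for (int n = 0; n < N; ++n) {
      pool2(act.slice(n), H, H, tmp);
      pooled.slice(n) = tmp;
    }
    Acts[l + 1] = pooled;
  }

  // flatten: (c3 * Hfl^2, N)
  const int c3 = cv[2].W.n_rows;
  const int flat = c3 * Hfl * Hfl;
  arma::mat F(flat, N);
  for (int n = 0; n < N; ++n)
    F.col(n) = arma::vectorise(Acts[3].slice(n));

  // FC stack
  arma::mat Zf1 = fc[0].W * F; Zf1.each_col() += fc[0].b;
  arma::mat xh1, H1pre; arma::vec mu1, var1;
  bn_fc_forward_train(Zf1, fc[0].gamma, fc[0].beta, xh1, H1pre, mu1, var1);
  arma::mat H1 = arma::clamp(H1pre, 0.0, arma::datum::inf);

  arma::mat Zf2 = fc[1].W * H1; Zf2.each_col() += fc[1].b;
  arma::mat xh2, H2pre; arma::vec mu2, var2;
  bn_fc_forward_train(Zf2, fc[1].gamma, fc[1].beta, xh2, H2pre, mu2, var2);
  arma::mat H2 = arma::clamp(H2pre, 0.0, arma::datum::inf);

  arma::rowvec zrow = Wout * H2 + bout;
  arma::rowvec prob = 1.0 / (1.0 + arma::exp(-zrow));
  prob = arma::clamp(prob, PROB_CLAMP, 1.0 - PROB_CLAMP);

  double loss = 0.0;
  for (int n = 0; n < N; ++n)
    loss += -yv(n) * std::log(prob(n)) - (1.0 - yv(n)) * std::log(1.0 - prob(n));
  loss /= N;

  // backward
  arma::rowvec dz(N);
  for (int n = 0; n < N; ++n) dz(n) = (prob(n) - yv(n)) / N;

  arma::mat dWout = dz * H2.t();
  double dbout = arma::accu(dz);
  arma::mat dH2 = Wout.t() * dz;

  arma::mat dA2 = dH2 % (H2pre > 0.0);
  arma::mat dZf2; arma::vec dg2, db2bn;
  bn_fc_backward(dA2, xh2, fc[1].gamma, var2, dZf2, dg2, db2bn);
  arma::mat dWf2 = dZf2 * H1.t();
  arma::vec dbf2 = arma::sum(dZf2, 1);
  arma::mat dH1 = fc[1].W.t() * dZf2;

  arma::mat dA1 = dH1 % (H1pre > 0.0);
  arma::mat dZf1; arma::vec dg1, db1bn;
  bn_fc_backward(dA1, xh1, fc[0].gamma, var1, dZf1, dg1, db1bn);
  arma::mat dWf1 = dZf1 * F.t();
  arma::vec dbf1 = arma::sum(dZf1, 1);
  arma::mat dF = fc[0].W.t() * dZf1;

  // un-flatten into grad wrt pooled block-3 output
  arma::cube dPool(c3, Hfl * Hfl, N);
  for (int n = 0; n < N; ++n)
    dPool.slice(n) = arma::reshape(dF.col(n), c3, Hfl * Hfl);

  // conv blocks backward
  arma::mat dWc[3]; arma::vec dbc[3], dgc[3], dbec[3];
  for (int l = 2; l >= 0; --l) {
    const int H = Hin[l], HW = H * H;
    const int outc = cv[l].W.n_rows;
    // pool backward, then dropout + ReLU
    arma::cube dRelu(outc, HW, N);
    arma::mat tmp;
    for (int n = 0; n < N; ++n) {
      unpool2(dPool.slice(n), H, H, tmp);
      dRelu.slice(n) = tmp % Mask[l].slice(n) %
                       arma::conv_to<arma::mat>::from(BnOut[l].slice(n) > 0.0);
    }
    arma::cube dZ;
    bn_conv_backward(dRelu, Xhat[l], cv[l].gamma, Var[l], dZ, dgc[l], dbec[l]);
    dWc[l].zeros(cv[l].W.n_rows, cv[l].W.n_cols);
    dbc[l].zeros(outc);
    const int inc = Acts[l].n_rows;
    arma::cube dAprev;
    if (l > 0) dAprev.set_size(inc, HW, N);
    arma::mat cols, dimg(inc, HW);
    for (int n = 0; n < N; ++n) {
      im2col3(Acts[l].slice(n), H, H, cols);
      dWc[l] += dZ.slice(n) * cols.t();
      dbc[l] += arma::sum(dZ.slice(n), 1);
      if (l > 0) {
        arma::mat dcols = cv[l].W.t() * dZ.slice(n);
        col2im3(dcols, H, H, dimg);
        dAprev.slice(n) = dimg;
      }
    }
    if (l > 0) dPool = dAprev;
  }

  auto conv_grad = [&](int l) {
    return List::create(_["W"] = dWc[l], _["b"] = dbc[l],
                        _["gamma"] = dgc[l], _["beta"] = dbec[l]);
  };
  List fc_grads = List::create(
      List::create(_["W"] = dWf1, _["b"] = dbf1, _["gamma"] = dg1, _["beta"] = db1bn),
      List::create(_["W"] = dWf2, _["b"] = dbf2, _["gamma"] = dg2, _["beta"] = db2bn));
  List grads = List::create(
      _["conv"] = List::create(conv_grad(0), conv_grad(1), conv_grad(2)),
      _["fc"] = fc_grads,
      _["out"] = List::create(_["W"] = dWout, _["b"] = dbout));
  List bn_stats = List::create(
      _["conv"] = List::create(
          List::create(_["mean"] = Mu[0], _["var"] = Var[0]),
          List::create(_["mean"] = Mu[1], _["var"] = Var[1]),
          List::create(_["mean"] = Mu[2], _["var"] = Var[2])),
      _["fc"] = List::create(
          List::create(_["mean"] = mu1, _["var"] = var1),
          List::create(_["mean"] = mu2, _["var"] = var2)));
  return List::create(_["loss"] = loss,
                      _["probs"] = NumericVector(prob.begin(), prob.end()),
                      _["grads"] = grads, _["bn"] = bn_stats);
}

// im2col for many images laid side by side in one matrix
// (channels, HW * N); output (channels*9, HW * N).
static void im2col3_batch(const arma::mat& A, int H, int W, int N,
                          arma::mat& out) {
  const int C = A.n_rows;
  const int HW = H * W;
  out.zeros(C * 9, (arma::uword)HW * N);
  for (int n = 0; n < N; ++n) {
    const arma::uword off = (arma::uword)HW * n;
    for (int c = 0; c < W; ++c) {
      for (int r = 0; r < H; ++r) {
        const arma::uword q = off + r + H * c;
        double* oc = out.colptr(q);
        for (int dc = -1; dc <= 1; ++dc) {
          const int cc = c + dc;
          if (cc < 0 || cc >= W) continue;
          for (int dr = -1; dr <= 1; ++dr) {
            const int rr = r + dr;
            if (rr < 0 || rr >= H) continue;
            const int krow = (dr + 1) + 3 * (dc + 1);
            std::memcpy(oc + krow * C, A.colptr(off + rr + H * cc),
                        C * sizeof(double));
          }
        }
      }
    }
  }
}

// Inference forward pass (running BN statistics, no dropout); the whole
// batch is processed with one gemm per layer.
// [[Rcpp::export]]
NumericVector cpp_cnn_infer(List params, NumericVector x) {
  List convs_in = params["conv"];
  List fcs_in = params["fc"];
  List out_in = params["out"];
  ConvLayer cv[3] = {conv_from_list(convs_in[0]), conv_from_list(convs_in[1]),
                     conv_from_list(convs_in[2])};
  FcLayer fc[2] = {fc_from_list(fcs_in[0]), fc_from_list(fcs_in[1])};
  arma::mat Wout = as<arma::mat>(out_in["W"]);
  double bout = as<double>(out_in["b"]);

  IntegerVector dims = x.attr("dim");
  const int w = dims[0], C_in = dims[2], N = dims[3];

  // lay all samples side by side: (C_in, w*w * N)
  arma::mat A(C_in, (arma::uword)w * w * N);
  {
    const double* px = x.begin();
    const int HW = w * w;
    for (int n = 0; n < N; ++n)
      for (int ch = 0; ch < C_in; ++ch)
        for (int q = 0; q < HW; ++q)
          A(ch, (arma::uword)HW * n + q) =
            px[q + (std::size_t)HW * ch + (std::size_t)HW * C_in * n];
  }

  int H = w;
  arma::mat cols;
  for (int l = 0; l < 3; ++l) {
    arma::vec invstd = 1.0 / arma::sqrt(cv[l].rvar + BN_EPS);
    arma::vec scale = cv[l].gamma % invstd;
    arma::vec shift = cv[l].beta + (cv[l].b - cv[l].rmean) % scale;
    im2col3_batch(A, H, H, N, cols);
    A = cv[l].W * cols;
    A.each_col() %= scale;
    A.each_col() += shift;
    A.transform([](double v) { return v > 0.0 ? v : 0.0; });
    // pool each sample
    const int outc = A.n_rows, HW = H * H, Ho = H / 2;
    arma::mat P(outc, (arma::uword)Ho * Ho * N);
    arma::mat tmp;
    for (int n = 0; n < N; ++n) {
      pool2(A.cols((arma::uword)HW * n, (arma::uword)HW * n + HW - 1), H, H, tmp);
      P.cols((arma::uword)Ho * Ho * n, (arma::uword)Ho * Ho * (n + 1) - 1) = tmp;
    }
    A = P;
    H = Ho;
  }
  const int c3 = cv[2].W.n_rows;
  const int flat = c3 * H * H;
  arma::mat F(flat, N);
  for (int n = 0; n < N; ++n)
    F.col(n) = arma::vectorise(A.cols((arma::uword)H * H * n,
                                      (arma::uword)H * H * (n + 1) - 1));

  for (int l = 0; l < 2; ++l) {
    arma::mat Z = fc[l].W * F;
    Z.each_col() += fc[l].b;
    arma::vec invstd = 1.0 / arma::sqrt(fc[l].rvar + BN_EPS);
    arma::vec scale = fc[l].gamma % invstd;
    arma::vec shift = fc[l].beta - fc[l].rmean % scale;
    Z.each_col() %= scale;
    Z.each_col() += shift;
    F = arma::clamp(Z, 0.0, arma::datum::inf);
  }
  arma::rowvec z = Wout * F + bout;
  arma::rowvec prob = 1.0 / (1.0 + arma::exp(-z));
  prob = arma::clamp(prob, PROB_CLAMP, 1.0 - PROB_CLAMP);
  return NumericVector(prob.begin(), prob.end());
}

// Build normalized two-channel windows around centers (0-based bins).
// M: dense symmetric contact matrix; track: per-bin accessibility.
// Each channel: v <- log10(1 + v), then v <- v / (1 + max(v)) per window.
// [[Rcpp::export]]
NumericVector cpp_build_windows(NumericMatrix M, NumericVector track,
                                IntegerVector iv, IntegerVector jv, int w) {
  const int N = iv.size();
  const int hw = (w - 1) / 2;
  const int plane = w * w;
  NumericVector out((R_xlen_t)plane * 2 * N);
  out.attr("dim") = IntegerVector::create(w, w, 2, N);
  double* po = out.begin();
  const double LOG10 = std::log(10.0);
  for (int n = 0; n < N; ++n) {
    const int ci = iv[n], cj = jv[n];
    double* hic = po + (std::size_t)plane * 2 * n;
    double* acc = hic + plane;
    double mx_h = 0.0, mx_a = 0.0;
    for (int c = 0; c < w; ++c) {
      const int cb = cj - hw + c;
      const double ty = track[cb];
      for (int r = 0; r < w; ++r) {
        const int rb = ci - hw + r;
        double vh = std::log1p(M(rb, cb)) / LOG10;
        double va = std::log1p(track[rb] * ty) / LOG10;
        hic[r + w * c] = vh;
        acc[r + w * c] = va;
        if (vh > mx_h) mx_h = vh;
        if (va > mx_a) mx_a = va;
      }
    }
    const double sh = 1.0 / (1.0 + mx_h), sa = 1.0 / (1.0 + mx_a);
    for (int q = 0; q < plane; ++q) { hic[q] *= sh; acc[q] *= sa; }
  }
  return out;
}
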