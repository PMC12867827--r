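// Elementwise / normalisation / attention kernels behind the R layer
// functions. Layouts match convops.cpp: batches are (H, W, C, N) arrays.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export(name = ".relu_fwd")]]
NumericVector relu_fwd(NumericVector x) {
  NumericVector y = clone(x);
  double* p = y.begin();
  for (R_xlen_t i = 0; i < y.size(); ++i)
    if (p[i] < 0) p[i] = 0;
  return y;
}

// [[Rcpp::export(name = ".relu_bwd")]]
NumericVector relu_bwd(NumericVector g, NumericVector y) {
  NumericVector dx = clone(g);
  double* p = dx.begin();
  const double* q = y.begin();
  for (R_xlen_t i = 0; i < dx.size(); ++i)
    if (q[i] <= 0) p[i] = 0;
  return dx;
}

// Batch norm forward. In training mode uses batch statistics over
// (H, W, N) per channel and updates the running mean/var (unbiased var);
// in eval mode uses the running statistics. With relu_out the rectifier is
// fused into the output (xhat is kept pre-rectifier for the backward pass).
// [[Rcpp::export(name = ".bn_fwd")]]
List bn_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
            NumericVector rmean, NumericVector rvar, bool train,
            double eps, double momentum, bool relu_out) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const R_xlen_t HW = (R_xlen_t)H * W;
  NumericVector y(x.size()), xhat(x.size());
  y.attr("dim") = xd;
  NumericVector mu(C), invstd(C);
  NumericVector newMean = clone(rmean), newVar = clone(rvar);
  const double M = (double)HW * N;
  for (int c = 0; c < C; ++c) {
    double m, v;
    if (train) {
      double s = 0, s2 = 0;
      for (int n = 0; n < N; ++n) {
        const double* p = x.begin() + ((R_xlen_t)n * C + c) * HW;
        for (R_xlen_t i = 0; i < HW; ++i) {
          s += p[i];
          s2 += p[i] * p[i];
        }
      }
      m = s / M;
      v = s2 / M - m * m;
      if (v < 0) v = 0;
      newMean[c] = (1 - momentum) * rmean[c] + momentum * m;
      newVar[c] = (1 - momentum) * rvar[c] +
        momentum * v * M / std::max(M - 1, 1.0);
    } else {
      m = rmean[c];
      v = rvar[c];
    }
    double is = 1.0 / std::sqrt(v + eps);
    mu[c] = m;
    invstd[c] = is;
    double ga = gamma[c], be = beta[c];
    for (int n = 0; n < N; ++n) {
      R_xlen_t off = ((R_xlen_t)n * C + c) * HW;
      const double* p = x.begin() + off;
      double* xh = xhat.begin() + off;
      double* yy = y.begin() + off;
      if (relu_out) {
        for (R_xlen_t i = 0; i < HW; ++i) {
          double z = (p[i] - m) * is;
          xh[i] = z;
          double val = z * ga + be;
          yy[i] = val > 0 ? val : 0;
        }
      } else {
        for (R_xlen_t i = 0; i < HW; ++i) {
          double z = (p[i] - m) * is;
          xh[i] = z;
          yy[i] = z * ga + be;
        }
      }
    }
  }
  xhat.attr("dim") = xd;
  return List::create(_["y"] = y, _["xhat"] = xhat, _["invstd"] = invstd,
                      _["mean"] = newMean, _["var"] = newVar);
}

// Batch norm backward. When reluY is non-empty it is the fused-rectifier
// output of the forward pass and g is first gated by reluY > 0.
// [[Rcpp::export(name = ".bn_bwd")]]
List bn_bwd(NumericVector g, NumericVector xhat, NumericVector invstd,
            NumericVector gamma, NumericVector reluY) {
  IntegerVector xd = g.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const R_xlen_t HW = (R_xlen_t)H * W;
  const double M = (double)HW * N;
  const bool gate = reluY.size() == g.size();
  NumericVector dx(g.size()), dgamma(C), dbeta(C);
  dx.attr("dim") = xd;
  for (int c = 0; c < C; ++c) {
    double sg = 0, sgx = 0;
    for (int n = 0; n < N; ++n) {
      R_xlen_t off = ((R_xlen_t)n * C + c) * HW;
      const double* gp = g.begin() + off;
      const double* xp = xhat.begin() + off;
      if (gate) {
        const double* yp = reluY.begin() + off;
        for (R_xlen_t i = 0; i < HW; ++i) {
          double gi = yp[i] > 0 ? gp[i] : 0;
          sg += gi;
          sgx += gi * xp[i];
        }
      } else {
        for (R_xlen_t i = 0; i < HW; ++i) {
          sg += gp[i];
          sgx += gp[i] * xp[i];
        }
      }
    }
    dbeta[c] = sg;
    dgamma[c] = sgx;
    double coef = gamma[c] * invstd[c];
    double gm = sg / M, gxm = sgx / M;
    for (int n = 0; n < N; ++n) {
      R_xlen_t off = ((R_xlen_t)n * C + c) * HW;
      const double* gp = g.begin() + off;
      const double* xp = xhat.begin() + off;
      double* dp = dx.begin() + off;
      if (gate) {
        const double* yp = reluY.begin() + off;
        for (R_xlen_t i = 0; i < HW; ++i) {
          double gi = yp[i] > 0 ? gp[i] : 0;
          dp[i] = coef * (gi - gm - xp[i] * gxm);
        }
      } else {
        for (R_xlen_t i = 0; i < HW; ++i)
          dp[i] = coef * (gp[i] - gm - xp[i] * gxm);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// Channel softmax over the third dimension of (H, W, K, N).
// [[Rcpp::export(name = ".softmax_ch")]]
NumericVector softmax_ch(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], K = xd[2], N = xd[3];
  const R_xlen_t HW = (R_xlen_t)H * W;
  NumericVector y(x.size());
  y.attr("dim") = xd;
  std::vector<double> buf(K);
  for (int n = 0; n < N; ++n) {
    const double* xb = x.begin() + (R_xlen_t)n * K * HW;
    double* yb = y.begin() + (R_xlen_t)n * K * HW;
    for (R_xlen_t i = 0; i < HW; ++i) {
      double m = xb[i];
      for (int k = 1; k < K; ++k) m = std::max(m, xb[i + k * HW]);
      double s = 0;
      for (int k = 0; k < K; ++k) {
        buf[k] = std::exp(xb[i + k * HW] - m);
        s += buf[k];
      }
      for (int k = 0; k < K; ++k) yb[i + k * HW] = buf[k] / s;
    }
  }
  return y;
}

// dL/dlogits = p * (g - sum_k p_k g_k), channel softmax backward.
// [[Rcpp::export(name = ".softmax_ch_bwd")]]
NumericVector softmax_ch_bwd(NumericVector g, NumericVector prob) {
  IntegerVector xd = g.attr("dim");
  int H = xd[0], W = xd[1], K = xd[2], N = xd[3];
  const R_xlen_t HW = (R_xlen_t)H * W;
  NumericVector dx(g.size());
  dx.attr("dim") = xd;
  for (int n = 0; n < N; ++n) {
    const double* gb = g.begin() + (R_xlen_t)n * K * HW;
    const double* pb = prob.begin() + (R_xlen_t)n * K * HW;
    double* db = dx.begin() + (R_xlen_t)n * K * HW;
    for (R_xlen_t i = 0; i < HW; ++i) {
      double tot = 0;
      for (int k = 0; k < K; ++k) tot += gb[i + k * HW] * pb[i + k * HW];
      for (int k = 0; k < K; ++k)
        db[i + k * HW] = pb[i + k * HW] * (gb[i + k * HW] - tot);
    }
  }
  return dx;
}
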