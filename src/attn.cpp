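// Scaled dot-product spatial attention kernels. The attention matrix is
// held transposed, as (M keys x HW queries) per sample, so the softmax over
// keys runs down contiguous columns and both products are single GEMMs.
// Like the conv kernels, the GEMM path is templated on precision.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

template <typename eT>
static void castCopy(const double* src, size_t n, arma::Mat<eT>& dst) {
  eT* p = dst.memptr();
  for (size_t i = 0; i < n; ++i) p[i] = (eT)src[i];
}

template <typename eT>
static void attn_fwd_impl(const double* q, const double* k, const double* v,
                          int HW, int M, int Ca, int N, double* fatt,
                          double* A) {
  const eT sc = (eT)(1.0 / std::sqrt((double)Ca));
  arma::Mat<eT> Q(HW, Ca), K(M, Ca), V(M, Ca), An(M, HW), F(HW, Ca);
  for (int n = 0; n < N; ++n) {
    castCopy(q + (size_t)n * HW * Ca, (size_t)HW * Ca, Q);
    castCopy(k + (size_t)n * M * Ca, (size_t)M * Ca, K);
    castCopy(v + (size_t)n * M * Ca, (size_t)M * Ca, V);
    An = (K * Q.t()) * sc;              // logits, keys down the columns
    for (int i = 0; i < HW; ++i) {
      eT* col = An.colptr(i);
      eT m = col[0];
      for (int j = 1; j < M; ++j) m = std::max(m, col[j]);
      eT s = 0;
      for (int j = 0; j < M; ++j) {
        col[j] = std::exp(col[j] - m);
        s += col[j];
      }
      eT inv = (eT)1 / s;
      for (int j = 0; j < M; ++j) col[j] *= inv;
    }
    F = An.t() * V;
    double* fo = fatt + (size_t)n * HW * Ca;
    for (size_t i = 0; i < (size_t)HW * Ca; ++i) fo[i] = (double)F.memptr()[i];
    double* ao = A + (size_t)n * HW * M;
    for (size_t i = 0; i < (size_t)HW * M; ++i) ao[i] = (double)An.memptr()[i];
  }
}

// q: (H, W, Ca, N); k, v: (H2, W2, Ca, N) (possibly pooled). Returns the
// attended features (H, W, Ca, N) and attention tensors (M, HW, N) whose
// columns are the row-stochastic attention weights of one query.
// [[Rcpp::export(name = ".attn_fwd")]]
List attn_fwd(NumericVector q, NumericVector k, NumericVector v,
              bool single) {
  IntegerVector qd = q.attr("dim"), kd = k.attr("dim");
  int H = qd[0], W = qd[1], Ca = qd[2], N = qd[3];
  int M = kd[0] * kd[1];
  const int HW = H * W;
  NumericVector fatt(q.size());
  fatt.attr("dim") = qd;
  NumericVector A((R_xlen_t)HW * M * N);
  A.attr("dim") = IntegerVector::create(M, HW, N);
  if (single)
    attn_fwd_impl<float>(q.begin(), k.begin(), v.begin(), HW, M, Ca, N,
                         fatt.begin(), A.begin());
  else
    attn_fwd_impl<double>(q.begin(), k.begin(), v.begin(), HW, M, Ca, N,
                          fatt.begin(), A.begin());
  return List::create(_["fatt"] = fatt, _["A"] = A);
}

template <typename eT>
static void attn_bwd_impl(const double* A, const double* q, const double* k,
                          const double* v, const double* dfatt, int HW,
                          int M, int Ca, int N, double* dq, double* dk,
                          double* dv) {
  const eT sc = (eT)(1.0 / std::sqrt((double)Ca));
  arma::Mat<eT> Q(HW, Ca), K(M, Ca), V(M, Ca), An(M, HW), dF(HW, Ca);
  for (int n = 0; n < N; ++n) {
    castCopy(q + (size_t)n * HW * Ca, (size_t)HW * Ca, Q);
    castCopy(k + (size_t)n * M * Ca, (size_t)M * Ca, K);
    castCopy(v + (size_t)n * M * Ca, (size_t)M * Ca, V);
    castCopy(A + (size_t)n * HW * M, (size_t)HW * M, An);
    castCopy(dfatt + (size_t)n * HW * Ca, (size_t)HW * Ca, dF);
    arma::Mat<eT> dV = An * dF;         // M x Ca
    arma::Mat<eT> dA = V * dF.t();      // M x HW
    // softmax backward per column: dlog = A % (dA - colsum(dA % A))
    for (int i = 0; i < HW; ++i) {
      const eT* a = An.colptr(i);
      eT* da = dA.colptr(i);
      eT tot = 0;
      for (int j = 0; j < M; ++j) tot += da[j] * a[j];
      for (int j = 0; j < M; ++j) da[j] = a[j] * (da[j] - tot);
    }
    arma::Mat<eT> dQ = (dA.t() * K) * sc;
    arma::Mat<eT> dK = (dA * Q) * sc;
    double* o;
    o = dq + (size_t)n * HW * Ca;
    for (size_t i = 0; i < (size_t)HW * Ca; ++i) o[i] = (double)dQ.memptr()[i];
    o = dk + (size_t)n * M * Ca;
    for (size_t i = 0; i < (size_t)M * Ca; ++i) o[i] = (double)dK.memptr()[i];
    o = dv + (size_t)n * M * Ca;
    for (size_t i = 0; i < (size_t)M * Ca; ++i) o[i] = (double)dV.memptr()[i];
  }
}

// Backward pass; A is the (M, HW, N) tensor stored by attn_fwd.
// [[Rcpp::export(name = ".attn_bwd")]]
List attn_bwd(NumericVector A, NumericVector q, NumericVector k,
              NumericVector v, NumericVector dfatt, bool single) {
  IntegerVector qd = q.attr("dim"), kd = k.attr("dim");
  int H = qd[0], W = qd[1], Ca = qd[2], N = qd[3];
  int M = kd[0] * kd[1];
  const int HW = H * W;
  NumericVector dq(q.size()), dk(k.size()), dv(v.size());
  dq.attr("dim") = qd;
  dk.attr("dim") = kd;
  dv.attr("dim") = kd;
  if (single)
    attn_bwd_impl<float>(A.begin(), q.begin(), k.begin(), v.begin(),
                         dfatt.begin(), HW, M, Ca, N, dq.begin(),
                         dk.begin(), dv.begin());
  else
    attn_bwd_impl<double>(A.begin(), q.begin(), k.begin(), v.begin(),
                          dfatt.begin(), HW, M, Ca, N, dq.begin(),
                          dk.begin(), dv.begin());
  return List::create(_["dq"] = dq, _["dk"] = dk, _["dv"] = dv);
}
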