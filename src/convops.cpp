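// BLAS-backed conv/pool kernels used by the network forward and backward
// passes. Array layout throughout: feature maps are R arrays of dimension
// (H, W, C, N) (column-major, H fastest); conv weights are (kh, kw, Cin,
// Cout). Convolutions are stride-1 with symmetric zero padding; transposed
// convolutions are the fixed 2x2/stride-2 upsampling used by the decoder.
// The GEMM path is templated on the scalar type: `single = true` computes
// in float32 (the standard training precision for this model family),
// `false` in float64 (used by the finite-difference gradient checks).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Fill the (HW x kh*kw*Cin) patch matrix for one sample, casting to eT.
template <typename eT>
static void im2col_t(const double* x, int H, int W, int Cin, int pad,
                     int kh, int kw, arma::Mat<eT>& col) {
  const int HW = H * W;
  for (int ci = 0; ci < Cin; ++ci) {
    const double* xc = x + (size_t)ci * HW;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        eT* dst = col.colptr(ki + kh * kj + kh * kw * ci);
        for (int j = 0; j < W; ++j) {
          int jj = j + kj - pad;
          eT* dcol = dst + (size_t)j * H;
          if (jj < 0 || jj >= W) {
            std::fill(dcol, dcol + H, (eT)0);
            continue;
          }
          const double* src = xc + (size_t)jj * H;
          int i0 = std::max(0, pad - ki);
          int i1 = std::min(H, H + pad - ki);  // exclusive
          for (int i = 0; i < i0; ++i) dcol[i] = 0;
          for (int i = i0; i < i1; ++i) dcol[i] = (eT)src[i + ki - pad];
          for (int i = i1; i < H; ++i) dcol[i] = 0;
        }
      }
    }
  }
}

// Scatter-add of the patch matrix back onto the (H, W, Cin) gradient image.
template <typename eT>
static void col2im_add(const arma::Mat<eT>& col, int H, int W, int Cin,
                       int pad, int kh, int kw, double* dx) {
  const int HW = H * W;
  for (int ci = 0; ci < Cin; ++ci) {
    double* dc = dx + (size_t)ci * HW;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const eT* src = col.colptr(ki + kh * kj + kh * kw * ci);
        for (int j = 0; j < W; ++j) {
          int jj = j + kj - pad;
          if (jj < 0 || jj >= W) continue;
          const eT* scol = src + (size_t)j * H;
          double* dcol = dc + (size_t)jj * H;
          int i0 = std::max(0, pad - ki);
          int i1 = std::min(H, H + pad - ki);
          for (int i = i0; i < i1; ++i) dcol[i + ki - pad] += (double)scol[i];
        }
      }
    }
  }
}

template <typename eT>
static void conv_fwd_impl(const double* x, const double* w, const double* b,
                          int H, int W, int Cin, int N, int kh, int kw,
                          int Cout, int pad, double* out) {
  const int HW = H * W;
  const size_t KC = (size_t)kh * kw * Cin;
  arma::Mat<eT> Wm(KC, Cout);
  for (size_t i = 0; i < KC * Cout; ++i) Wm.memptr()[i] = (eT)w[i];
  arma::Row<eT> bv(Cout);
  for (int c = 0; c < Cout; ++c) bv[c] = (eT)b[c];
  arma::Mat<eT> col(HW, KC);
  arma::Mat<eT> Y(HW, Cout);
  for (int n = 0; n < N; ++n) {
    im2col_t<eT>(x + (size_t)n * HW * Cin, H, W, Cin, pad, kh, kw, col);
    Y = col * Wm;
    Y.each_row() += bv;
    double* o = out + (size_t)n * HW * Cout;
    const eT* yp = Y.memptr();
    for (size_t i = 0; i < (size_t)HW * Cout; ++i) o[i] = (double)yp[i];
  }
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                         int pad, bool single) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  if (wd[2] != Cin) stop("channel mismatch: input has %d, weights expect %d",
                         Cin, (int)wd[2]);
  NumericVector out((R_xlen_t)H * W * Cout * N);
  out.attr("dim") = IntegerVector::create(H, W, Cout, N);
  if (single)
    conv_fwd_impl<float>(x.begin(), w.begin(), b.begin(), H, W, Cin, N,
                         kh, kw, Cout, pad, out.begin());
  else
    conv_fwd_impl<double>(x.begin(), w.begin(), b.begin(), H, W, Cin, N,
                          kh, kw, Cout, pad, out.begin());
  return out;
}

template <typename eT>
static void conv_bwd_impl(const double* x, const double* w,
                          const double* gout, int H, int W, int Cin, int N,
                          int kh, int kw, int Cout, int pad, bool need_dx,
                          double* dx, double* dw, double* db) {
  const int HW = H * W;
  const size_t KC = (size_t)kh * kw * Cin;
  arma::Mat<eT> Wm(KC, Cout);
  for (size_t i = 0; i < KC * Cout; ++i) Wm.memptr()[i] = (eT)w[i];
  arma::Mat<eT> dWm(KC, Cout, arma::fill::zeros);
  arma::Row<eT> dbv(Cout, arma::fill::zeros);
  arma::Mat<eT> col(HW, KC);
  arma::Mat<eT> G(HW, Cout);
  arma::Mat<eT> dcol(HW, KC);
  for (int n = 0; n < N; ++n) {
    const double* gp = gout + (size_t)n * HW * Cout;
    eT* gm = G.memptr();
    for (size_t i = 0; i < (size_t)HW * Cout; ++i) gm[i] = (eT)gp[i];
    im2col_t<eT>(x + (size_t)n * HW * Cin, H, W, Cin, pad, kh, kw, col);
    dWm += col.t() * G;
    dbv += arma::sum(G, 0);
    if (need_dx) {
      dcol = G * Wm.t();
      col2im_add<eT>(dcol, H, W, Cin, pad, kh, kw,
                     dx + (size_t)n * HW * Cin);
    }
  }
  for (size_t i = 0; i < KC * Cout; ++i) dw[i] = (double)dWm.memptr()[i];
  for (int c = 0; c < Cout; ++c) db[c] = (double)dbv[c];
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector gout,
                int pad, bool need_dx, bool single) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  NumericVector dx(need_dx ? x.size() : 0);
  NumericVector dw(w.size());
  NumericVector db(Cout);
  if (single)
    conv_bwd_impl<float>(x.begin(), w.begin(), gout.begin(), H, W, Cin, N,
                         kh, kw, Cout, pad, need_dx, dx.begin(), dw.begin(),
                         db.begin());
  else
    conv_bwd_impl<double>(x.begin(), w.begin(), gout.begin(), H, W, Cin, N,
                          kh, kw, Cout, pad, need_dx, dx.begin(), dw.begin(),
                          db.begin());
  if (need_dx) dx.attr("dim") = xd;
  dw.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Transposed convolution, kernel 2x2, stride 2: (H, W, Cin) -> (2H, 2W, Cout).
// [[Rcpp::export(name = ".convt2d_fwd")]]
NumericVector convt2d_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  int Cout = wd[3];
  const int HW = H * W, H2 = 2 * H, W2 = 2 * W;
  NumericVector out((R_xlen_t)H2 * W2 * Cout * N);
  out.attr("dim") = IntegerVector::create(H2, W2, Cout, N);
  for (int n = 0; n < N; ++n) {
    arma::mat X(const_cast<double*>(x.begin()) + (size_t)n * HW * Cin,
                HW, Cin, false);
    for (int dj = 0; dj < 2; ++dj) {
      for (int di = 0; di < 2; ++di) {
        arma::mat Wsub(Cin, Cout);
        for (int co = 0; co < Cout; ++co)
          for (int ci = 0; ci < Cin; ++ci)
            Wsub(ci, co) = w[di + 2 * dj + 4 * ci + (size_t)4 * Cin * co];
        arma::mat Y = X * Wsub;  // HW x Cout
        for (int co = 0; co < Cout; ++co) {
          double* o = out.begin() + (size_t)n * H2 * W2 * Cout +
                      (size_t)co * H2 * W2;
          const double* yc = Y.colptr(co);
          double bias = b[co];
          for (int j = 0; j < W; ++j) {
            double* ocol = o + (size_t)(2 * j + dj) * H2 + di;
            const double* ycol = yc + (size_t)j * H;
            for (int i = 0; i < H; ++i) ocol[2 * i] = ycol[i] + bias;
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".convt2d_bwd")]]
List convt2d_bwd(NumericVector x, NumericVector w, NumericVector gout) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  int Cout = wd[3];
  const int HW = H * W, H2 = 2 * H, W2 = 2 * W;
  NumericVector dx(x.size()), dw(w.size()), db(Cout);
  for (int n = 0; n < N; ++n) {
    arma::mat X(const_cast<double*>(x.begin()) + (size_t)n * HW * Cin,
                HW, Cin, false);
    arma::mat dX(dx.begin() + (size_t)n * HW * Cin, HW, Cin, false, true);
    for (int dj = 0; dj < 2; ++dj) {
      for (int di = 0; di < 2; ++di) {
        arma::mat G(HW, Cout);
        for (int co = 0; co < Cout; ++co) {
          const double* g = gout.begin() + (size_t)n * H2 * W2 * Cout +
                            (size_t)co * H2 * W2;
          double* gc = G.colptr(co);
          for (int j = 0; j < W; ++j) {
            const double* gcol = g + (size_t)(2 * j + dj) * H2 + di;
            double* gdst = gc + (size_t)j * H;
            for (int i = 0; i < H; ++i) gdst[i] = gcol[2 * i];
          }
        }
        arma::mat Wsub(Cin, Cout);
        for (int co = 0; co < Cout; ++co)
          for (int ci = 0; ci < Cin; ++ci)
            Wsub(ci, co) = w[di + 2 * dj + 4 * ci + (size_t)4 * Cin * co];
        dX += G * Wsub.t();
        arma::mat dWsub = X.t() * G;
        for (int co = 0; co < Cout; ++co) {
          for (int ci = 0; ci < Cin; ++ci)
            dw[di + 2 * dj + 4 * ci + (size_t)4 * Cin * co] += dWsub(ci, co);
          db[co] += arma::accu(G.col(co));
        }
      }
    }
  }
  dx.attr("dim") = xd;
  dw.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 max pooling, stride 2. Returns pooled values and the within-window
// argmax (0..3, column-major within the window) for the backward pass.
// [[Rcpp::export(name = ".maxpool2_fwd")]]
List maxpool2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx(y.size());
  size_t m = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xp = x.begin() + (size_t)(n * C + c) * H * W;
      for (int j = 0; j < Wo; ++j) {
        for (int i = 0; i < Ho; ++i, ++m) {
          const double* p = xp + (size_t)(2 * j) * H + 2 * i;
          double v = p[0];
          int a = 0;
          if (p[1] > v) { v = p[1]; a = 1; }
          if (p[H] > v) { v = p[H]; a = 2; }
          if (p[H + 1] > v) { v = p[H + 1]; a = 3; }
          y[m] = v;
          idx[m] = a;
        }
      }
    }
  }
  idx.attr("dim") = y.attr("dim");
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_bwd")]]
NumericVector maxpool2_bwd(IntegerVector idx, NumericVector gout,
                           int H, int W) {
  IntegerVector gd = gout.attr("dim");
  int Ho = gd[0], Wo = gd[1], C = gd[2], N = gd[3];
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  size_t m = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      double* xp = dx.begin() + (size_t)(n * C + c) * H * W;
      for (int j = 0; j < Wo; ++j) {
        for (int i = 0; i < Ho; ++i, ++m) {
          int a = idx[m];
          double* p = xp + (size_t)(2 * j + a / 2) * H + 2 * i + a % 2;
          *p += gout[m];
        }
      }
    }
  }
  return dx;
}
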