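// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Layer primitives for the U-net. All tensors are R arrays in column-major
// (H, W, C, N) layout. Convolutions are zero-padded "same" with square odd
// kernels, realized as im2col + GEMM. Backward passes are exact adjoints /
// gradients of the forward ops.

static inline void im2col(const double* x, int H, int W, int C, int k,
                          arma::mat& col) {
  const int pad = k / 2;
  const int HW = H * W;
  for (int ci = 0; ci < C; ++ci) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int r = ki + k * kj + k * k * ci;
        double* dst = col.colptr(0) + r; // stride col.n_rows between pixels
        for (int j = 0; j < W; ++j) {
          const int jj = j + kj - pad;
          for (int i = 0; i < H; ++i) {
            const int ii = i + ki - pad;
            const int q = i + H * j;
            double v = 0.0;
            if (ii >= 0 && ii < H && jj >= 0 && jj < W)
              v = x[ii + H * jj + HW * ci];
            dst[(size_t)q * col.n_rows] = v;
          }
        }
      }
    }
  }
}

static inline void col2im(const arma::mat& col, int H, int W, int C, int k,
                          double* dx) {
  const int pad = k / 2;
  const int HW = H * W;
  for (int ci = 0; ci < C; ++ci) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int r = ki + k * kj + k * k * ci;
        const double* src = col.colptr(0) + r;
        for (int j = 0; j < W; ++j) {
          const int jj = j + kj - pad;
          if (jj < 0 || jj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int ii = i + ki - pad;
            if (ii < 0 || ii >= H) continue;
            const int q = i + H * j;
            dx[ii + H * jj + HW * ci] += src[(size_t)q * col.n_rows];
          }
        }
      }
    }
  }
}

static IntegerVector dims4(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d (H, W, C, N) array");
  return d;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(const NumericVector& x, const NumericVector& w,
                             const NumericVector& bias) {
  IntegerVector dx = dims4(x), dw = dims4(w);
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int k = dw[0], Cin = dw[2], Cout = dw[3];
  if (dw[1] != k || Cin != C) stop("weight/input channel mismatch");
  const int HW = H * W;
  NumericVector out(Rf_allocVector(REALSXP, (R_xlen_t)HW * Cout * N));
  out.attr("dim") = IntegerVector::create(H, W, Cout, N);
  const arma::mat Wm(const_cast<double*>(w.begin()), k * k * Cin, Cout, false, true);
  arma::mat col(k * k * Cin, HW);
  const bool has_b = bias.size() == Cout;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)HW * C * n, H, W, C, k, col);
    arma::mat Y = col.t() * Wm; // HW x Cout
    double* o = out.begin() + (size_t)HW * Cout * n;
    for (int co = 0; co < Cout; ++co) {
      const double b = has_b ? bias[co] : 0.0;
      const double* yc = Y.colptr(co);
      double* oc = o + (size_t)HW * co;
      for (int q = 0; q < HW; ++q) oc[q] = yc[q] + b;
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(const NumericVector& x, const NumericVector& w,
                    const NumericVector& dy, const bool need_dx,
                    const bool need_db) {
  IntegerVector dxd = dims4(x), dw = dims4(w), dyd = dims4(dy);
  const int H = dxd[0], W = dxd[1], C = dxd[2], N = dxd[3];
  const int k = dw[0], Cout = dw[3];
  const int HW = H * W;
  if (dyd[2] != Cout || dyd[0] != H || dyd[1] != W || dyd[3] != N)
    stop("dy shape mismatch");
  const arma::mat Wm(const_cast<double*>(w.begin()), k * k * C, Cout, false, true);
  arma::mat dWm(k * k * C, Cout, arma::fill::zeros);
  NumericVector dbias(Cout);
  NumericVector dxv;
  if (need_dx) {
    dxv = NumericVector(Rf_allocVector(REALSXP, (R_xlen_t)HW * C * N));
    std::fill(dxv.begin(), dxv.end(), 0.0);
    dxv.attr("dim") = IntegerVector::create(H, W, C, N);
  }
  arma::mat col(k * k * C, HW);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)HW * C * n, H, W, C, k, col);
    const arma::mat dYm(const_cast<double*>(dy.begin()) + (size_t)HW * Cout * n,
                        HW, Cout, false, true);
    dWm += col * dYm;
    if (need_db)
      for (int co = 0; co < Cout; ++co)
        dbias[co] += arma::accu(dYm.col(co));
    if (need_dx) {
      arma::mat dcol = Wm * dYm.t(); // (k*k*C) x HW
      col2im(dcol, H, W, C, k, dxv.begin() + (size_t)HW * C * n);
    }
  }
  NumericVector dwv(dWm.begin(), dWm.end());
  dwv.attr("dim") = dw;
  return List::create(_["dw"] = dwv, _["db"] = dbias,
                      _["dx"] = need_dx ? (SEXP)dxv : R_NilValue);
}

// 2x2 max pooling, stride 2. Returns pooled values and 0-based argmax linear
// indices into each sample's (H, W, C) block for the backward pass.
// [[Rcpp::export]]
List cpp_maxpool_fwd(const NumericVector& x) {
  IntegerVector d = dims4(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  if (H % 2 || W % 2) stop("max pooling requires even spatial dimensions");
  const int Ho = H / 2, Wo = W / 2, HWo = Ho * Wo, HW = H * W;
  NumericVector y(Rf_allocVector(REALSXP, (R_xlen_t)HWo * C * N));
  IntegerVector idx(Rf_allocVector(INTSXP, (R_xlen_t)HWo * C * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n) {
    const double* xs = x.begin() + (size_t)HW * C * n;
    double* ys = y.begin() + (size_t)HWo * C * n;
    int* is = idx.begin() + (size_t)HWo * C * n;
    for (int c = 0; c < C; ++c) {
      for (int j = 0; j < Wo; ++j) {
        for (int i = 0; i < Ho; ++i) {
          const int i0 = 2 * i, j0 = 2 * j;
          int best = i0 + H * j0 + HW * c;
          double bv = xs[best];
          const int cand[3] = { i0 + 1 + H * j0 + HW * c,
                                i0 + H * (j0 + 1) + HW * c,
                                i0 + 1 + H * (j0 + 1) + HW * c };
          for (int t = 0; t < 3; ++t)
            if (xs[cand[t]] > bv) { bv = xs[cand[t]]; best = cand[t]; }
          ys[i + Ho * j + HWo * c] = bv;
          is[i + Ho * j + HWo * c] = best;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(const NumericVector& dy, const IntegerVector& idx,
                              const int H, const int W) {
  IntegerVector d = dims4(dy);
  const int Ho = d[0], Wo = d[1], C = d[2], N = d[3];
  const int HWo = Ho * Wo, HW = H * W;
  NumericVector dx(Rf_allocVector(REALSXP, (R_xlen_t)HW * C * N));
  std::fill(dx.begin(), dx.end(), 0.0);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n) {
    const double* dys = dy.begin() + (size_t)HWo * C * n;
    const int* is = idx.begin() + (size_t)HWo * C * n;
    double* dxs = dx.begin() + (size_t)HW * C * n;
    for (R_xlen_t q = 0; q < (R_xlen_t)HWo * C; ++q) dxs[is[q]] += dys[q];
  }
  return dx;
}

// Bilinear x2 upsampling with half-pixel alignment (source coordinate
// (o + 0.5)/2 - 0.5 for output index o), edges clamped.
static inline void up2_weights(int o, int n_in, int& i0, int& i1, double& w1) {
  double s = 0.5 * (o + 0.5) - 0.5;
  if (s < 0) s = 0;
  if (s > n_in - 1) s = n_in - 1;
  i0 = (int)std::floor(s);
  i1 = i0 + 1 < n_in ? i0 + 1 : i0;
  w1 = s - i0;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_fwd(const NumericVector& x) {
  IntegerVector d = dims4(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Ho = 2 * H, Wo = 2 * W, HW = H * W, HWo = Ho * Wo;
  NumericVector y(Rf_allocVector(REALSXP, (R_xlen_t)HWo * C * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  std::vector<int> ri0(Ho), ri1(Ho), cj0(Wo), cj1(Wo);
  std::vector<double> rw(Ho), cw(Wo);
  for (int o = 0; o < Ho; ++o) up2_weights(o, H, ri0[o], ri1[o], rw[o]);
  for (int o = 0; o < Wo; ++o) up2_weights(o, W, cj0[o], cj1[o], cw[o]);
  for (R_xlen_t cn = 0; cn < (R_xlen_t)C * N; ++cn) {
    const double* xs = x.begin() + HW * cn;
    double* ys = y.begin() + HWo * cn;
    for (int j = 0; j < Wo; ++j) {
      const int j0 = cj0[j], j1 = cj1[j];
      const double wj = cw[j];
      for (int i = 0; i < Ho; ++i) {
        const double wi = rw[i];
        ys[i + Ho * j] =
          (1 - wi) * (1 - wj) * xs[ri0[i] + H * j0] +
          wi * (1 - wj) * xs[ri1[i] + H * j0] +
          (1 - wi) * wj * xs[ri0[i] + H * j1] +
          wi * wj * xs[ri1[i] + H * j1];
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_bwd(const NumericVector& dy) {
  IntegerVector d = dims4(dy);
  const int Ho = d[0], Wo = d[1], C = d[2], N = d[3];
  const int H = Ho / 2, W = Wo / 2, HW = H * W, HWo = Ho * Wo;
  NumericVector dx(Rf_allocVector(REALSXP, (R_xlen_t)HW * C * N));
  std::fill(dx.begin(), dx.end(), 0.0);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  std::vector<int> ri0(Ho), ri1(Ho), cj0(Wo), cj1(Wo);
  std::vector<double> rw(Ho), cw(Wo);
  for (int o = 0; o < Ho; ++o) up2_weights(o, H, ri0[o], ri1[o], rw[o]);
  for (int o = 0; o < Wo; ++o) up2_weights(o, W, cj0[o], cj1[o], cw[o]);
  for (R_xlen_t cn = 0; cn < (R_xlen_t)C * N; ++cn) {
    const double* dys = dy.begin() + HWo * cn;
    double* dxs = dx.begin() + HW * cn;
    for (int j = 0; j < Wo; ++j) {
      const int j0 = cj0[j], j1 = cj1[j];
      const double wj = cw[j];
      for (int i = 0; i < Ho; ++i) {
        const double wi = rw[i];
        const double g = dys[i + Ho * j];
        dxs[ri0[i] + H * j0] += (1 - wi) * (1 - wj) * g;
        dxs[ri1[i] + H * j0] += wi * (1 - wj) * g;
        dxs[ri0[i] + H * j1] += (1 - wi) * wj * g;
        dxs[ri1[i] + H * j1] += wi * wj * g;
      }
    }
  }
  return dx;
}
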