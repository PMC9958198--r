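// Hot-path kernels for the fusion network: 2-D/1-D convolution and max
// pooling, forward and backward.  Tensors arrive as R arrays laid out
// (channels, height, width, batch), i.e. channel index fastest.  Convolution
// uses an im2col buffer per batch element and BLAS GEMM via Armadillo.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void get_dims4(const NumericVector& x, int d[4]) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 4) stop("expected a 4-d array");
  for (int i = 0; i < 4; ++i) d[i] = dm[i];
}

// Build im2col matrix for one batch element.
// K has (Cin*kh*kw) rows and (Ho*Wo) cols; row order: channel fastest,
// then kernel row offset, then kernel col offset (matches R array
// W[cout, cin, a, b] flattened to (Cout, Cin*kh*kw)).
static void im2col(const double* xb, int Cin, int H, int W,
                   int kh, int kw, int ph, int pw,
                   int Ho, int Wo, arma::mat& K) {
  for (int j = 0; j < Wo; ++j) {
    for (int i = 0; i < Ho; ++i) {
      double* col = K.colptr(j * Ho + i);  // we order output pixels (i fastest)
      int r = 0;
      for (int b = 0; b < kw; ++b) {
        int wj = j + b - pw;
        for (int a = 0; a < kh; ++a) {
          int hi = i + a - ph;
          if (hi < 0 || hi >= H || wj < 0 || wj >= W) {
            for (int c = 0; c < Cin; ++c) col[r++] = 0.0;
          } else {
            const double* src = xb + (size_t)Cin * (hi + (size_t)H * wj);
            for (int c = 0; c < Cin; ++c) col[r++] = src[c];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".cppConvForward")]]
NumericVector cppConvForward(NumericVector x, NumericVector Wt,
                             NumericVector bias, int kh, int kw,
                             int ph, int pw) {
  int d[4];
  get_dims4(x, d);
  int Cin = d[0], H = d[1], W = d[2], B = d[3];
  int Cout = bias.size();
  int Ho = H + 2 * ph - kh + 1;
  int Wo = W + 2 * pw - kw + 1;
  if (Ho < 1 || Wo < 1) stop("kernel larger than (padded) input");
  if ((int)Wt.size() != Cout * Cin * kh * kw)
    stop("weight size mismatch");

  NumericVector y((size_t)Cout * Ho * Wo * B);
  y.attr("dim") = IntegerVector::create(Cout, Ho, Wo, B);

  arma::mat Wm(const_cast<double*>(Wt.begin()), Cout, Cin * kh * kw,
               false, true);
  arma::colvec bv(const_cast<double*>(bias.begin()), Cout, false, true);
  arma::mat K(Cin * kh * kw, Ho * Wo);

  // im2col orders output pixels with i (height) fastest, identical to the
  // (Cout, Ho, Wo) layout of y, so the GEMM result is written contiguously.
  for (int b = 0; b < B; ++b) {
    const double* xb = x.begin() + (size_t)Cin * H * W * b;
    im2col(xb, Cin, H, W, kh, kw, ph, pw, Ho, Wo, K);
    arma::mat yb(y.begin() + (size_t)Cout * Ho * Wo * b, Cout, Ho * Wo,
                 false, true);
    yb = Wm * K;
    yb.each_col() += bv;
  }
  return y;
}

// [[Rcpp::export(name = ".cppConvBackward")]]
List cppConvBackward(NumericVector x, NumericVector Wt, NumericVector dy,
                     int kh, int kw, int ph, int pw,
                     bool needParam, bool needInput) {
  int d[4];
  get_dims4(x, d);
  int Cin = d[0], H = d[1], W = d[2], B = d[3];
  int od[4];
  get_dims4(dy, od);
  int Cout = od[0], Ho = od[1], Wo = od[2];
  if (od[3] != B) stop("batch size mismatch");

  arma::mat Wm(const_cast<double*>(Wt.begin()), Cout, Cin * kh * kw,
               false, true);
  arma::mat K(Cin * kh * kw, Ho * Wo);
  arma::mat dW(Cout, Cin * kh * kw, arma::fill::zeros);
  arma::colvec db(Cout, arma::fill::zeros);

  NumericVector dx;
  if (needInput) {
    dx = NumericVector((size_t)Cin * H * W * B);
    dx.attr("dim") = IntegerVector::create(Cin, H, W, B);
  }
  arma::mat dK(Cin * kh * kw, Ho * Wo);

  for (int b = 0; b < B; ++b) {
    const double* xb = x.begin() + (size_t)Cin * H * W * b;
    arma::mat dyb(const_cast<double*>(dy.begin()) +
                      (size_t)Cout * Ho * Wo * b,
                  Cout, Ho * Wo, false, true);
    if (needParam) {
      im2col(xb, Cin, H, W, kh, kw, ph, pw, Ho, Wo, K);
      dW += dyb * K.t();
      db += arma::sum(dyb, 1);
    }
    if (needInput) {
      dK = Wm.t() * dyb;  // col2im scatter-add
      double* dxb = dx.begin() + (size_t)Cin * H * W * b;
      for (int j = 0; j < Wo; ++j) {
        for (int i = 0; i < Ho; ++i) {
          const double* col = dK.colptr(j * Ho + i);
          int r = 0;
          for (int kb = 0; kb < kw; ++kb) {
            int wj = j + kb - pw;
            for (int a = 0; a < kh; ++a) {
              int hi = i + a - ph;
              if (hi < 0 || hi >= H || wj < 0 || wj >= W) {
                r += Cin;
              } else {
                double* dst = dxb + (size_t)Cin * (hi + (size_t)H * wj);
                for (int c = 0; c < Cin; ++c) dst[c] += col[r++];
              }
            }
          }
        }
      }
    }
  }

  List out;
  if (needParam) {
    NumericVector dWr(dW.begin(), dW.end());
    dWr.attr("dim") = IntegerVector::create(Cout, Cin, kh, kw);
    out["dW"] = dWr;
    out["db"] = NumericVector(db.begin(), db.end());
  }
  if (needInput) out["dx"] = dx;
  return out;
}

// Max pooling with window (rh, rw) in {1,2} x {1,2}, stride equal to the
// window; trailing rows/columns that do not fill a window are dropped.
// Returns pooled values and 1-based flat indices of the winners for the
// backward pass.
// [[Rcpp::export(name = ".cppPoolForward")]]
List cppPoolForward(NumericVector x, int rh, int rw) {
  int d[4];
  get_dims4(x, d);
  int C = d[0], H = d[1], W = d[2], B = d[3];
  int Ho = H / rh, Wo = W / rw;

  NumericVector y((size_t)C * Ho * Wo * B);
  IntegerVector idx((size_t)C * Ho * Wo * B);
  y.attr("dim") = IntegerVector::create(C, Ho, Wo, B);

  const double* xp = x.begin();
  size_t k = 0;
  for (int b = 0; b < B; ++b) {
    size_t ob = (size_t)C * H * W * b;
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        for (int c = 0; c < C; ++c) {
          size_t best = ob + c + (size_t)C * ((size_t)i * rh +
                          (size_t)H * (size_t)j * rw);
          double bv = xp[best];
          for (int db2 = 0; db2 < rw; ++db2) {
            for (int da = 0; da < rh; ++da) {
              size_t pos = ob + c + (size_t)C * ((size_t)(i * rh + da) +
                             (size_t)H * (size_t)(j * rw + db2));
              if (xp[pos] > bv) { bv = xp[pos]; best = pos; }
            }
          }
          y[k] = bv;
          idx[k] = (int)(best + 1);
          ++k;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".cppPoolBackward")]]
NumericVector cppPoolBackward(NumericVector dy, IntegerVector idx,
                              IntegerVector inDim) {
  size_t n = (size_t)inDim[0] * inDim[1] * inDim[2] * inDim[3];
  NumericVector dx(n);
  dx.attr("dim") = inDim;
  for (R_xlen_t k = 0; k < dy.size(); ++k) dx[idx[k] - 1] += dy[k];
  return dx;
}
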