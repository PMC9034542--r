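// 3x3 same-padding convolution, forward and backward, for [H, W, C, N]
// column-major arrays. im2col + GEMM; single-threaded and deterministic.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// M: (H*W) x (9*C), row p = h + H*w, col r = kh + 3*kw + 9*c.
// Matches the column-major flattening of a [3, 3, C, Cout] weight array.
static void im2col3(const double* x, int H, int W, int C, arma::mat& M) {
  M.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int kw = 0; kw < 3; ++kw) {
      for (int kh = 0; kh < 3; ++kh) {
        int col = kh + 3 * kw + 9 * c;
        double* m = M.colptr(col);
        int dh = kh - 1, dw = kw - 1;
        for (int w = 0; w < W; ++w) {
          int sw = w + dw;
          if (sw < 0 || sw >= W) continue;
          const double* src = xc + (size_t)H * sw;
          double* dst = m + (size_t)H * w;
          int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
          for (int h = h0; h < h1; ++h) dst[h] = src[h + dh];
        }
      }
    }
  }
}

// Scatter-add transpose of im2col3.
static void col2im3(const arma::mat& M, int H, int W, int C, double* dx) {
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)H * W * c;
    for (int kw = 0; kw < 3; ++kw) {
      for (int kh = 0; kh < 3; ++kh) {
        int col = kh + 3 * kw + 9 * c;
        const double* m = M.colptr(col);
        int dh = kh - 1, dw = kw - 1;
        for (int w = 0; w < W; ++w) {
          int sw = w + dw;
          if (sw < 0 || sw >= W) continue;
          double* dst = xc + (size_t)H * sw;
          const double* src = m + (size_t)H * w;
          int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
          for (int h = h0; h < h1; ++h) dst[h + dh] += src[h];
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv3x3_fwd")]]
NumericVector conv3x3_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Cout = wd[3];
  if (wd[2] != C) stop("channel mismatch between input and kernel");
  arma::mat Wm(const_cast<double*>(w.begin()), 9 * C, Cout, false, true);
  arma::rowvec bv(const_cast<double*>(b.begin()), Cout, false, true);
  NumericVector out((size_t)H * W * Cout * N);
  out.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat M(H * W, 9 * C);
  for (int n = 0; n < N; ++n) {
    im2col3(x.begin() + (size_t)H * W * C * n, H, W, C, M);
    arma::mat Y = M * Wm;
    Y.each_row() += bv;
    std::copy(Y.begin(), Y.end(), out.begin() + (size_t)H * W * Cout * n);
  }
  return out;
}

// [[Rcpp::export(name = ".conv3x3_bwd")]]
List conv3x3_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Cout = wd[3];
  arma::mat Wm(const_cast<double*>(w.begin()), 9 * C, Cout, false, true);
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = xd;
  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  NumericVector db(Cout);
  arma::mat dWm(dw.begin(), 9 * C, Cout, false, true);
  arma::rowvec dbv(db.begin(), Cout, false, true);
  arma::mat M(H * W, 9 * C);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)H * W * C * n;
    arma::mat dY(const_cast<double*>(dy.begin()) + (size_t)H * W * Cout * n,
                 H * W, Cout, false, true);
    im2col3(xn, H, W, C, M);
    dWm += M.t() * dY;
    dbv += arma::sum(dY, 0);
    arma::mat dM = dY * Wm.t();
    col2im3(dM, H, W, C, dx.begin() + (size_t)H * W * C * n);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}
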