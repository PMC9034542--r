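// Per-channel primitives on [H, W, C, N] arrays (column-major), used by
// batch normalization and bias application without large R temporaries.
#include <Rcpp.h>
using namespace Rcpp;

// y[...,c,n] = x[...,c,n] * scale[c] + shift[c] (either may be NULL)
// [[Rcpp::export(name = ".ch_affine")]]
NumericVector ch_affine(NumericVector x, Nullable<NumericVector> scale,
                        Nullable<NumericVector> shift) {
  IntegerVector d = x.attr("dim");
  size_t hw = (size_t)d[0] * d[1];
  int C = d[2], N = d[3];
  NumericVector out(x.size());
  out.attr("dim") = d;
  bool has_s = scale.isNotNull(), has_b = shift.isNotNull();
  NumericVector sv = has_s ? NumericVector(scale) : NumericVector(0);
  NumericVector bv = has_b ? NumericVector(shift) : NumericVector(0);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      double s = has_s ? sv[c] : 1.0;
      double b = has_b ? bv[c] : 0.0;
      size_t off = hw * ((size_t)c + (size_t)C * n);
      for (size_t i = 0; i < hw; ++i) op[off + i] = xp[off + i] * s + b;
    }
  }
  return out;
}

// per-channel sum over (H, W, N)
// [[Rcpp::export(name = ".ch_sum")]]
NumericVector ch_sum(NumericVector x) {
  IntegerVector d = x.attr("dim");
  size_t hw = (size_t)d[0] * d[1];
  int C = d[2], N = d[3];
  NumericVector out(C);
  const double* xp = x.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      size_t off = hw * ((size_t)c + (size_t)C * n);
      double s = 0;
      for (size_t i = 0; i < hw; ++i) s += xp[off + i];
      out[c] += s;
    }
  }
  return out;
}

// per-channel sum of x*y over (H, W, N)
// [[Rcpp::export(name = ".ch_dot")]]
NumericVector ch_dot(NumericVector x, NumericVector y) {
  IntegerVector d = x.attr("dim");
  size_t hw = (size_t)d[0] * d[1];
  int C = d[2], N = d[3];
  NumericVector out(C);
  const double* xp = x.begin();
  const double* yp = y.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      size_t off = hw * ((size_t)c + (size_t)C * n);
      double s = 0;
      for (size_t i = 0; i < hw; ++i) s += xp[off + i] * yp[off + i];
      out[c] += s;
    }
  }
  return out;
}

// centered per-channel: y = (x - mu[c]) and per-channel sum of squares
// [[Rcpp::export(name = ".ch_center")]]
List ch_center(NumericVector x, NumericVector mu) {
  IntegerVector d = x.attr("dim");
  size_t hw = (size_t)d[0] * d[1];
  int C = d[2], N = d[3];
  NumericVector out(x.size());
  out.attr("dim") = d;
  NumericVector ss(C);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      size_t off = hw * ((size_t)c + (size_t)C * n);
      double m = mu[c], s = 0;
      for (size_t i = 0; i < hw; ++i) {
        double v = xp[off + i] - m;
        op[off + i] = v;
        s += v * v;
      }
      ss[c] += s;
    }
  }
  return List::create(_["centered"] = out, _["sumsq"] = ss);
}

// leaky ReLU forward (alpha = 0 gives plain ReLU)
// [[Rcpp::export(name = ".lrelu_fwd")]]
NumericVector lrelu_fwd(NumericVector x, double alpha) {
  NumericVector out(x.size());
  out.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    double v = x[i];
    out[i] = v > 0 ? v : alpha * v;
  }
  return out;
}

// leaky ReLU backward
// [[Rcpp::export(name = ".lrelu_bwd")]]
NumericVector lrelu_bwd(NumericVector x, NumericVector g, double alpha) {
  NumericVector out(x.size());
  out.attr("dim") = g.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i)
    out[i] = x[i] > 0 ? g[i] : alpha * g[i];
  return out;
}

// concatenate along the channel axis (dim 3 of [H, W, C, N])
// [[Rcpp::export(name = ".cat_ch")]]
NumericVector cat_ch(List xs) {
  int K = xs.size();
  std::vector<NumericVector> vs(K);
  std::vector<int> cs(K);
  IntegerVector d0 = as<NumericVector>(xs[0]).attr("dim");
  int H = d0[0], W = d0[1], N = d0[3], Ctot = 0;
  for (int k = 0; k < K; ++k) {
    vs[k] = as<NumericVector>(xs[k]);
    IntegerVector dk = vs[k].attr("dim");
    cs[k] = dk[2];
    Ctot += dk[2];
  }
  size_t hw = (size_t)H * W;
  NumericVector out(hw * Ctot * N);
  out.attr("dim") = IntegerVector::create(H, W, Ctot, N);
  double* op = out.begin();
  for (int n = 0; n < N; ++n) {
    size_t at = hw * (size_t)Ctot * n;
    for (int k = 0; k < K; ++k) {
      const double* src = vs[k].begin() + hw * (size_t)cs[k] * n;
      std::copy(src, src + hw * cs[k], op + at);
      at += hw * cs[k];
    }
  }
  return out;
}

// split a gradient along the channel axis into pieces of the given sizes
// [[Rcpp::export(name = ".split_ch")]]
List split_ch(NumericVector g, IntegerVector sizes) {
  IntegerVector d = g.attr("dim");
  int H = d[0], W = d[1], Ctot = d[2], N = d[3];
  size_t hw = (size_t)H * W;
  int K = sizes.size();
  List out(K);
  int c0 = 0;
  for (int k = 0; k < K; ++k) {
    int ck = sizes[k];
    NumericVector piece(hw * (size_t)ck * N);
    piece.attr("dim") = IntegerVector::create(H, W, ck, N);
    double* pp = piece.begin();
    for (int n = 0; n < N; ++n) {
      const double* src = g.begin() + hw * ((size_t)c0 + (size_t)Ctot * n);
      std::copy(src, src + hw * ck, pp + hw * (size_t)ck * n);
    }
    out[k] = piece;
    c0 += ck;
  }
  return out;
}
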