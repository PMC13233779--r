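// Gather/scatter primitives that lower 1-D convolution onto BLAS matrix
// products. Arrays follow R's column-major [batch, channel, time] layout:
// X[b, c, t] sits at b + B*(c + C*t). The im2col matrix has rows indexed
// by (b, t_out) (b fastest) and columns by (c, k) (c fastest), matching
// the weight layout W[c + Cin*(k-1), co].

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector X, int B, int Cin, int T,
                         int K, int stride, int pad, int t_out) {
  NumericMatrix out(B * t_out, Cin * K);
  const double *x = X.begin();
  double *o = out.begin();
  for (int k = 0; k < K; ++k) {
    for (int c = 0; c < Cin; ++c) {
      double *col = o + (long)(c + Cin * k) * B * t_out;
      for (int t = 0; t < t_out; ++t) {
        int tt = t * stride - pad + k;
        double *dst = col + (long)t * B;
        if (tt < 0 || tt >= T) {
          for (int b = 0; b < B; ++b) dst[b] = 0.0;
        } else {
          const double *src = x + (long)B * (c + (long)Cin * tt);
          for (int b = 0; b < B; ++b) dst[b] = src[b];
        }
      }
    }
  }
  return out;
}

// [B*t_out, Cout] matrix (rows b fastest, then t) -> [B, Cout, t_out] array
// [[Rcpp::export]]
NumericVector permute_out_cpp(NumericMatrix Y, int B, int t_out, int Cout) {
  NumericVector out(B * Cout * t_out);
  const double *y = Y.begin();
  double *o = out.begin();
  for (int co = 0; co < Cout; ++co) {
    const double *ycol = y + (long)co * B * t_out;
    for (int t = 0; t < t_out; ++t) {
      const double *src = ycol + (long)t * B;
      double *dst = o + (long)B * (co + (long)Cout * t);
      for (int b = 0; b < B; ++b) dst[b] = src[b];
    }
  }
  return out;
}

// [B, Cout, t_out] array -> [B*t_out, Cout] matrix (inverse of the above)
// [[Rcpp::export]]
NumericMatrix permute_in_cpp(NumericVector dY, int B, int Cout, int t_out) {
  NumericMatrix out(B * t_out, Cout);
  const double *y = dY.begin();
  double *o = out.begin();
  for (int co = 0; co < Cout; ++co) {
    double *ocol = o + (long)co * B * t_out;
    for (int t = 0; t < t_out; ++t) {
      const double *src = y + (long)B * (co + (long)Cout * t);
      double *dst = ocol + (long)t * B;
      for (int b = 0; b < B; ++b) dst[b] = src[b];
    }
  }
  return out;
}

// scatter-add the columns of dXcol back onto the input grid (adjoint of
// im2col); returns a [B, Cin, T] array
// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix dXcol, int B, int Cin, int T,
                         int K, int stride, int pad, int t_out) {
  NumericVector dX(B * Cin * T);
  const double *src0 = dXcol.begin();
  double *dx = dX.begin();
  for (int k = 0; k < K; ++k) {
    for (int c = 0; c < Cin; ++c) {
      const double *col = src0 + (long)(c + Cin * k) * B * t_out;
      for (int t = 0; t < t_out; ++t) {
        int tt = t * stride - pad + k;
        if (tt < 0 || tt >= T) continue;
        const double *src = col + (long)t * B;
        double *dst = dx + (long)B * (c + (long)Cin * tt);
        for (int b = 0; b < B; ++b) dst[b] += src[b];
      }
    }
  }
  return dX;
}
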