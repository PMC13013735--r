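// Hot inner kernels of the dense-flow estimator: separable correlation
// with replicate boundary and bilinear field sampling. Semantics mirror
// the R definitions in utils-image.R.
#include <Rcpp.h>
using namespace Rcpp;

// out(i, j) = sum_k w[k] * X(i, clamp(j + d[k]))
// [[Rcpp::export]]
NumericMatrix corr_x_cpp(const NumericMatrix& X, const NumericVector& w,
                         const IntegerVector& d) {
  const int nr = X.nrow(), nc = X.ncol(), nk = w.size();
  NumericMatrix out(nr, nc);
  for (int k = 0; k < nk; ++k) {
    const double wk = w[k];
    const int dk = d[k];
    for (int j = 0; j < nc; ++j) {
      int s = j + dk;
      if (s < 0) s = 0; else if (s >= nc) s = nc - 1;
      const double* src = &X(0, s);
      double* dst = &out(0, j);
      for (int i = 0; i < nr; ++i) dst[i] += wk * src[i];
    }
  }
  return out;
}

// out(i, j) = sum_k w[k] * X(clamp(i + d[k]), j)
// [[Rcpp::export]]
NumericMatrix corr_y_cpp(const NumericMatrix& X, const NumericVector& w,
                         const IntegerVector& d) {
  const int nr = X.nrow(), nc = X.ncol(), nk = w.size();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    const double* src = &X(0, j);
    double* dst = &out(0, j);
    for (int k = 0; k < nk; ++k) {
      const double wk = w[k];
      const int dk = d[k];
      for (int i = 0; i < nr; ++i) {
        int s = i + dk;
        if (s < 0) s = 0; else if (s >= nr) s = nr - 1;
        dst[i] += wk * src[s];
      }
    }
  }
  return out;
}

// bilinear interpolation of F at 0-based fractional (x, y), clamped
// [[Rcpp::export]]
NumericVector bilinear_cpp(const NumericMatrix& F, const NumericVector& xs,
                           const NumericVector& ys) {
  const int nr = F.nrow(), nc = F.ncol();
  const R_xlen_t n = xs.size();
  NumericVector out(n);
  for (R_xlen_t p = 0; p < n; ++p) {
    double x = xs[p], y = ys[p];
    if (x < 0) x = 0; else if (x > nc - 1) x = nc - 1;
    if (y < 0) y = 0; else if (y > nr - 1) y = nr - 1;
    const int x0 = (int)x, y0 = (int)y;
    const int x1 = x0 + 1 < nc ? x0 + 1 : nc - 1;
    const int y1 = y0 + 1 < nr ? y0 + 1 : nr - 1;
    const double fx = x - x0, fy = y - y0;
    out[p] = (1 - fy) * ((1 - fx) * F(y0, x0) + fx * F(y0, x1)) +
             fy * ((1 - fx) * F(y1, x0) + fx * F(y1, x1));
  }
  return out;
}
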