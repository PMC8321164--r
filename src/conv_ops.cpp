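#include <Rcpp.h>
using namespace Rcpp;

// Gather rows of x into the im2col matrix. `src` maps each output row to a
// 1-based row of x, or 0 for a zero-padded position. x is (C*H*W) x N with
// channel-fastest layout; the output is (length(src)) x N.
// [[Rcpp::export]]
NumericMatrix gather_rows(const NumericMatrix& x, const IntegerVector& src) {
  const int g = src.size(), n = x.ncol(), rows = x.nrow();
  NumericMatrix out(g, n);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int j = 0; j < n; ++j) {
    const double* xc = xp + (R_xlen_t)j * rows;
    double* oc = op + (R_xlen_t)j * g;
    for (int i = 0; i < g; ++i) {
      const int s = src[i];
      oc[i] = s ? xc[s - 1] : 0.0;
    }
  }
  return out;
}

// 2x2 stride-2 max pooling given the four corner row-index vectors
// (1-based, disjoint). Returns the pooled matrix and the winning corner
// (1..4) per output element for the backward pass.
// [[Rcpp::export]]
List maxpool_fwd(const NumericMatrix& x, const IntegerVector& r1,
                 const IntegerVector& r2, const IntegerVector& r3,
                 const IntegerVector& r4) {
  const int m = r1.size(), n = x.ncol(), rows = x.nrow();
  NumericMatrix out(m, n);
  IntegerMatrix which(m, n);
  const double* xp = x.begin();
  for (int j = 0; j < n; ++j) {
    const double* xc = xp + (R_xlen_t)j * rows;
    for (int i = 0; i < m; ++i) {
      double best = xc[r1[i] - 1];
      int w = 1;
      double v = xc[r2[i] - 1];
      if (v > best) { best = v; w = 2; }
      v = xc[r3[i] - 1];
      if (v > best) { best = v; w = 3; }
      v = xc[r4[i] - 1];
      if (v > best) { best = v; w = 4; }
      out(i, j) = best;
      which(i, j) = w;
    }
  }
  return List::create(_["out"] = out, _["which"] = which);
}

// [[Rcpp::export]]
NumericMatrix maxpool_bwd(const NumericMatrix& dy, const IntegerMatrix& which,
                          const IntegerVector& r1, const IntegerVector& r2,
                          const IntegerVector& r3, const IntegerVector& r4,
                          const int nin) {
  const int m = r1.size(), n = dy.ncol();
  NumericMatrix dx(nin, n);
  for (int j = 0; j < n; ++j) {
    for (int i = 0; i < m; ++i) {
      int r;
      switch (which(i, j)) {
        case 1: r = r1[i]; break;
        case 2: r = r2[i]; break;
        case 3: r = r3[i]; break;
        default: r = r4[i];
      }
      dx(r - 1, j) = dy(i, j);
    }
  }
  return dx;
}

// Block-mean downsample of an H x W matrix by integer factors fy, fx.
// [[Rcpp::export]]
NumericMatrix block_mean(const NumericMatrix& x, const int fy, const int fx) {
  const int ho = x.nrow() / fy, wo = x.ncol() / fx;
  NumericMatrix out(ho, wo);
  const double scale = 1.0 / (fy * fx);
  for (int j = 0; j < wo; ++j) {
    for (int jj = 0; jj < fx; ++jj) {
      const double* xc = &x(0, j * fx + jj);
      double* oc = &out(0, j);
      for (int i = 0; i < ho; ++i) {
        double s = 0.0;
        const double* xr = xc + i * fy;
        for (int ii = 0; ii < fy; ++ii) s += xr[ii];
        oc[i] += s;
      }
    }
  }
  for (int j = 0; j < wo; ++j)
    for (int i = 0; i < ho; ++i) out(i, j) *= scale;
  return out;
}

// BT.601 luminance of an H x W x 3 array (flattened plane-major).
// [[Rcpp::export]]
NumericMatrix luminance_cpp(const NumericVector& img, const int h,
                            const int w) {
  NumericMatrix out(h, w);
  const double* p = img.begin();
  const R_xlen_t n = (R_xlen_t)h * w;
  double* o = out.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    o[i] = 0.299 * p[i] + 0.587 * p[i + n] + 0.114 * p[i + 2 * n];
  }
  return out;
}
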