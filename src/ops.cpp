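// Elementwise / row-wise layer primitives used by the transformer stack.
// These are single-pass replacements for R expressions that would allocate
// several large temporaries per call.

#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// fast exp (see attention.cpp): 2^z split, degree-8 Taylor on the fraction
static inline double fast_exp_(double x) {
  if (x < -700.0) return 0.0;
  if (x > 700.0) return std::exp(x);
  const double y = x * 1.4426950408889634;
  const double fi = std::floor(y);
  const double t = (y - fi) * 0.6931471805599453;
  const double p = 1.0 + t * (1.0 + t * (0.5 + t * (1.0 / 6 +
      t * (1.0 / 24 + t * (1.0 / 120 + t * (1.0 / 720 +
      t * (1.0 / 5040 + t * (1.0 / 40320))))))));
  return std::ldexp(p, (int) fi);
}

// GELU, sigmoid approximation x * sigmoid(1.702 x); returns the activation
// and the cached sigmoid term for the backward pass
// [[Rcpp::export]]
List gelu_fwd_cpp(const NumericMatrix& X) {
  const R_xlen_t n = (R_xlen_t) X.nrow() * X.ncol();
  NumericMatrix out(X.nrow(), X.ncol()), tt(X.nrow(), X.ncol());
  const double* x = &X[0];
  double* o = &out[0];
  double* t = &tt[0];
  for (R_xlen_t i = 0; i < n; ++i) {
    const double xi = x[i];
    const double s = 1.0 / (1.0 + fast_exp_(-1.702 * xi));
    t[i] = s;
    o[i] = xi * s;
  }
  return List::create(_["out"] = out, _["t"] = tt);
}

// dY * gelu'(x) given the cached sigmoid term
// [[Rcpp::export]]
NumericMatrix gelu_bwd_cpp(const NumericMatrix& X, const NumericMatrix& T,
                           const NumericMatrix& dY) {
  const R_xlen_t n = (R_xlen_t) X.nrow() * X.ncol();
  NumericMatrix out(X.nrow(), X.ncol());
  const double* x = &X[0];
  const double* t = &T[0];
  const double* d = &dY[0];
  double* o = &out[0];
  for (R_xlen_t i = 0; i < n; ++i) {
    const double s = t[i];
    o[i] = d[i] * (s + 1.702 * x[i] * s * (1.0 - s));
  }
  return out;
}

// adds b to each row of M IN PLACE and returns M; the caller must own M as
// a freshly allocated temporary (as after a matrix product)
// [[Rcpp::export]]
NumericMatrix add_bias_inplace(NumericMatrix M, const NumericVector& b) {
  const int n = M.nrow(), d = M.ncol();
  for (int j = 0; j < d; ++j) {
    const double bj = b[j];
    double* col = &M[0] + (size_t) j * n;
    for (int i = 0; i < n; ++i) col[i] += bj;
  }
  return M;
}

// row-wise layer normalization: Y = (X - mean) / sd * g + b
// [[Rcpp::export]]
List layernorm_fwd_cpp(const NumericMatrix& X, const NumericVector& g,
                       const NumericVector& b, double eps = 1e-12) {
  const int n = X.nrow(), d = X.ncol();
  NumericMatrix Y(n, d), xhat(n, d);
  NumericVector istd(n);
  std::vector<double> mu(n, 0.0), v(n, 0.0);
  const double* x = &X[0];
  for (int j = 0; j < d; ++j) {
    const double* col = x + (size_t) j * n;
    for (int i = 0; i < n; ++i) mu[i] += col[i];
  }
  for (int i = 0; i < n; ++i) mu[i] /= d;
  for (int j = 0; j < d; ++j) {
    const double* col = x + (size_t) j * n;
    for (int i = 0; i < n; ++i) {
      const double c = col[i] - mu[i];
      v[i] += c * c;
    }
  }
  for (int i = 0; i < n; ++i) istd[i] = 1.0 / std::sqrt(v[i] / d + eps);
  for (int j = 0; j < d; ++j) {
    const double* col = x + (size_t) j * n;
    double* xh = &xhat[0] + (size_t) j * n;
    double* y = &Y[0] + (size_t) j * n;
    const double gj = g[j], bj = b[j];
    for (int i = 0; i < n; ++i) {
      const double h = (col[i] - mu[i]) * istd[i];
      xh[i] = h;
      y[i] = h * gj + bj;
    }
  }
  return List::create(_["Y"] = Y, _["xhat"] = xhat, _["istd"] = istd);
}

// backward of layernorm_fwd_cpp
// [[Rcpp::export]]
List layernorm_bwd_cpp(const NumericMatrix& dY, const NumericMatrix& xhat,
                       const NumericVector& istd, const NumericVector& g) {
  const int n = dY.nrow(), d = dY.ncol();
  NumericMatrix dX(n, d);
  NumericVector dg(d), db(d);
  std::vector<double> m1(n, 0.0), m2(n, 0.0);  // row means of dxhat, dxhat*xhat
  for (int j = 0; j < d; ++j) {
    const double* dy = &dY[0] + (size_t) j * n;
    const double* xh = &xhat[0] + (size_t) j * n;
    const double gj = g[j];
    double sg = 0, sb = 0;
    for (int i = 0; i < n; ++i) {
      const double dxh = dy[i] * gj;
      m1[i] += dxh;
      m2[i] += dxh * xh[i];
      sg += dy[i] * xh[i];
      sb += dy[i];
    }
    dg[j] = sg;
    db[j] = sb;
  }
  for (int i = 0; i < n; ++i) { m1[i] /= d; m2[i] /= d; }
  for (int j = 0; j < d; ++j) {
    const double* dy = &dY[0] + (size_t) j * n;
    const double* xh = &xhat[0] + (size_t) j * n;
    double* dx = &dX[0] + (size_t) j * n;
    const double gj = g[j];
    for (int i = 0; i < n; ++i)
      dx[i] = istd[i] * (dy[i] * gj - m1[i] - xh[i] * m2[i]);
  }
  return List::create(_["dX"] = dX, _["dg"] = dg, _["db"] = db);
}
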