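// Hot-path kernels: fused batch-normalisation passes and the column
// expansion of the temporal convolution.  Everything else stays in R.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
List bn_fwd_train_cpp(NumericMatrix x, NumericVector gamma,
                      NumericVector beta, double eps) {
  const int n = x.nrow(), f = x.ncol();
  NumericMatrix xhat(n, f), out(n, f);
  NumericVector mu(f), v(f), s(f);
  for (int j = 0; j < f; ++j) {
    const double *xj = &x(0, j);
    double m = 0.0;
    for (int i = 0; i < n; ++i) m += xj[i];
    m /= n;
    double vv = 0.0;
    for (int i = 0; i < n; ++i) { const double d = xj[i] - m; vv += d * d; }
    vv /= n;
    const double sd = std::sqrt(vv + eps);
    const double g = gamma[j], b = beta[j];
    double *xh = &xhat(0, j), *oj = &out(0, j);
    for (int i = 0; i < n; ++i) {
      const double z = (xj[i] - m) / sd;
      xh[i] = z;
      oj[i] = z * g + b;
    }
    mu[j] = m; v[j] = vv; s[j] = sd;
  }
  return List::create(_["out"] = out, _["xhat"] = xhat, _["mu"] = mu,
                      _["var"] = v, _["s"] = s);
}

// [[Rcpp::export]]
List bn_bwd_cpp(NumericMatrix dout, NumericMatrix xhat, NumericVector s,
                NumericVector gamma) {
  const int n = dout.nrow(), f = dout.ncol();
  NumericMatrix dx(n, f);
  NumericVector dgamma(f), dbeta(f);
  for (int j = 0; j < f; ++j) {
    const double *dj = &dout(0, j), *xh = &xhat(0, j);
    double sum_d = 0.0, sum_dx = 0.0;
    for (int i = 0; i < n; ++i) { sum_d += dj[i]; sum_dx += dj[i] * xh[i]; }
    const double g = gamma[j];
    const double cm1 = g * sum_d / n, cm2 = g * sum_dx / n;
    const double inv_s = 1.0 / s[j];
    double *dxj = &dx(0, j);
    for (int i = 0; i < n; ++i) {
      dxj[i] = (g * dj[i] - cm1 - xh[i] * cm2) * inv_s;
    }
    dgamma[j] = sum_dx;
    dbeta[j] = sum_d;
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// xtpad: (n, Tp, C) array of the zero-padded signal; returns the
// (n*T*C) x kt matrix whose product with the kernel bank gives the
// temporal convolution at every output position
// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector xtpad, int n, int tp, int c,
                         int t_out, int kt) {
  NumericMatrix out((R_xlen_t)n * t_out * c, kt);
  const double *src = xtpad.begin();
  double *dst = out.begin();
  for (int j = 0; j < kt; ++j) {
    for (int ch = 0; ch < c; ++ch) {
      for (int t = 0; t < t_out; ++t) {
        const double *s0 = src + (R_xlen_t)n * (t + j + (R_xlen_t)tp * ch);
        double *d0 = dst + (R_xlen_t)j * n * t_out * c +
          (R_xlen_t)n * (t + (R_xlen_t)t_out * ch);
        std::copy(s0, s0 + n, d0);
      }
    }
  }
  return out;
}
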