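// Per-channel batch normalisation over (H, W, C, N) arrays.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

static void dims4(const Rcpp::NumericVector& x, size_t& hw, int& C, int& N) {
  const Rcpp::IntegerVector d(x.attr("dim"));
  hw = (size_t)d[0] * d[1];
  C = d[2];
  N = d[3];
}

// Channel means and (biased) variances.
// [[Rcpp::export(name = ".bn_stats")]]
Rcpp::List bn_stats(const Rcpp::NumericVector& z) {
  size_t hw; int C, N;
  dims4(z, hw, C, N);
  Rcpp::NumericVector mean(C), var(C);
  const double m = (double)hw * N;
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double* p = z.begin() + hw * (c + (size_t)C * n);
      for (size_t i = 0; i < hw; ++i) { s += p[i]; s2 += p[i] * p[i]; }
    }
    mean[c] = s / m;
    double v = s2 / m - mean[c] * mean[c];
    var[c] = v > 0 ? v : 0;
  }
  return Rcpp::List::create(Rcpp::Named("mean") = mean,
                            Rcpp::Named("var") = var);
}

// y = gamma * xhat + beta with xhat = (z - mean) * inv_sd; returns y and xhat.
// [[Rcpp::export(name = ".bn_apply")]]
Rcpp::List bn_apply(const Rcpp::NumericVector& z,
                    const Rcpp::NumericVector& mean,
                    const Rcpp::NumericVector& inv_sd,
                    const Rcpp::NumericVector& gamma,
                    const Rcpp::NumericVector& beta,
                    const bool want_xhat) {
  size_t hw; int C, N;
  dims4(z, hw, C, N);
  Rcpp::NumericVector y(Rcpp::no_init(z.size()));
  y.attr("dim") = z.attr("dim");
  Rcpp::NumericVector xhat;
  if (want_xhat) {
    xhat = Rcpp::NumericVector(Rcpp::no_init(z.size()));
    xhat.attr("dim") = z.attr("dim");
  }
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t off = hw * (c + (size_t)C * n);
      const double* p = z.begin() + off;
      double* py = y.begin() + off;
      const double mu = mean[c], is = inv_sd[c], g = gamma[c], b = beta[c];
      if (want_xhat) {
        double* px = xhat.begin() + off;
        for (size_t i = 0; i < hw; ++i) {
          px[i] = (p[i] - mu) * is;
          py[i] = g * px[i] + b;
        }
      } else {
        for (size_t i = 0; i < hw; ++i) py[i] = g * (p[i] - mu) * is + b;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("xhat") = xhat);
}

// Batch-norm backward: given upstream gradient g and cached xhat,
//   gz = inv_sd/m * (m * ghat - sum(ghat) - xhat * sum(ghat * xhat)),
// with ghat = gamma * g; also returns d(gamma), d(beta).
// [[Rcpp::export(name = ".bn_backward")]]
Rcpp::List bn_backward(const Rcpp::NumericVector& g,
                       const Rcpp::NumericVector& xhat,
                       const Rcpp::NumericVector& gamma,
                       const Rcpp::NumericVector& inv_sd) {
  size_t hw; int C, N;
  dims4(g, hw, C, N);
  const double m = (double)hw * N;
  Rcpp::NumericVector ggamma(C), gbeta(C);
  Rcpp::NumericVector gz(Rcpp::no_init(g.size()));
  gz.attr("dim") = g.attr("dim");
  for (int c = 0; c < C; ++c) {
    double sg = 0, sgx = 0;
    for (int n = 0; n < N; ++n) {
      const size_t off = hw * (c + (size_t)C * n);
      const double* pg = g.begin() + off;
      const double* px = xhat.begin() + off;
      for (size_t i = 0; i < hw; ++i) { sg += pg[i]; sgx += pg[i] * px[i]; }
    }
    ggamma[c] = sgx;
    gbeta[c] = sg;
    const double ga = gamma[c];
    const double k1 = inv_sd[c] * ga;                 // per-element term
    const double k2 = inv_sd[c] * ga * sg / m;        // mean correction
    const double k3 = inv_sd[c] * ga * sgx / m;       // variance correction
    for (int n = 0; n < N; ++n) {
      const size_t off = hw * (c + (size_t)C * n);
      const double* pg = g.begin() + off;
      const double* px = xhat.begin() + off;
      double* pz = gz.begin() + off;
      for (size_t i = 0; i < hw; ++i) pz[i] = k1 * pg[i] - k2 - k3 * px[i];
    }
  }
  return Rcpp::List::create(Rcpp::Named("gz") = gz,
                            Rcpp::Named("ggamma") = ggamma,
                            Rcpp::Named("gbeta") = gbeta);
}
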