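// Coordinate-descent core of the elastic-net penalized logistic regression.
// Mirrors the documented objective in R/elastic-net.R: mean negative
// log-likelihood + lambda * (alpha * L1 + (1 - alpha)/2 * L2), intercept
// unpenalized, predictors pre-standardized by the caller.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double soft(double u, double g) {
  if (u > g) return u - g;
  if (u < -g) return u + g;
  return 0.0;
}

// Fits the whole (decreasing) lambda path with warm starts.
// [[Rcpp::export(name = ".enet_logistic_path")]]
List enet_logistic_path(const NumericMatrix& xs, const NumericVector& y,
                        const NumericVector& lambda, double alpha,
                        double beta0_init, double tol, int max_outer,
                        int max_inner) {
  const int n = xs.nrow(), p = xs.ncol(), nl = lambda.size();
  NumericMatrix betas(p, nl);
  NumericVector b0s(nl);
  IntegerVector outers(nl);

  std::vector<double> beta(p, 0.0), eta(n), w(n), res(n), wxx(p);
  double b0 = beta0_init;

  for (int k = 0; k < nl; ++k) {
    const double l1 = lambda[k] * alpha;
    const double l2 = lambda[k] * (1.0 - alpha);
    int outer = 0;
    for (outer = 1; outer <= max_outer; ++outer) {
      // IRLS linearization at the current fit
      double wsum = 0.0;
      for (int i = 0; i < n; ++i) {
        double e = b0;
        for (int j = 0; j < p; ++j) e += xs(i, j) * beta[j];
        double mu = 1.0 / (1.0 + std::exp(-e));
        double wi = mu * (1.0 - mu);
        if (wi < 1e-6) wi = 1e-6;
        w[i] = wi;
        wsum += wi;
        res[i] = (y[i] - mu) / wi; // working response minus eta
      }
      for (int j = 0; j < p; ++j) {
        double s = 0.0;
        for (int i = 0; i < n; ++i) s += w[i] * xs(i, j) * xs(i, j);
        wxx[j] = s / n;
      }
      std::vector<double> beta_old(beta);
      double b0_old = b0;
      for (int inner = 0; inner < max_inner; ++inner) {
        double max_delta = 0.0;
        for (int j = 0; j < p; ++j) {
          double s = 0.0;
          for (int i = 0; i < n; ++i) s += w[i] * xs(i, j) * res[i];
          double u = s / n + wxx[j] * beta[j];
          double bj = soft(u, l1) / (wxx[j] + l2);
          double d = bj - beta[j];
          if (d != 0.0) {
            for (int i = 0; i < n; ++i) res[i] -= xs(i, j) * d;
            if (std::fabs(d) > max_delta) max_delta = std::fabs(d);
            beta[j] = bj;
          }
        }
        double s0 = 0.0;
        for (int i = 0; i < n; ++i) s0 += w[i] * res[i];
        double d0 = s0 / wsum;
        if (d0 != 0.0) {
          b0 += d0;
          for (int i = 0; i < n; ++i) res[i] -= d0;
          if (std::fabs(d0) > max_delta) max_delta = std::fabs(d0);
        }
        if (max_delta < tol) break;
      }
      double chg = std::fabs(b0 - b0_old);
      for (int j = 0; j < p; ++j) {
        double d = std::fabs(beta[j] - beta_old[j]);
        if (d > chg) chg = d;
      }
      if (chg < tol && outer > 1) break;
    }
    for (int j = 0; j < p; ++j) betas(j, k) = beta[j];
    b0s[k] = b0;
    outers[k] = outer;
  }
  return List::create(_["beta"] = betas, _["b0"] = b0s,
                      _["n_outer"] = outers);
}
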