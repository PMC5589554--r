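#include <Rcpp.h>
using namespace Rcpp;

static inline double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// L1-penalized logistic regression by proximal Newton with inner
// coordinate descent (objective: mean negative log-likelihood +
// lambda * sum |beta_j| over penalized columns; intercept never shrunk).
// [[Rcpp::export]]
List cd_logistic_cpp(NumericMatrix X, NumericVector y, double lambda,
                     IntegerVector penalty, NumericVector beta_init,
                     double intercept_init, double tol, int max_outer,
                     int max_inner) {
  const int n = X.nrow(), p = X.ncol();
  NumericVector beta = clone(beta_init);
  double b0 = intercept_init;
  NumericVector eta(n), w(n), z(n), r(n);
  bool converged = false;
  int outer = 0;

  for (outer = 0; outer < max_outer; ++outer) {
    // quadratic approximation at current (b0, beta)
    for (int i = 0; i < n; ++i) {
      double e = b0;
      for (int j = 0; j < p; ++j) e += X(i, j) * beta[j];
      eta[i] = e;
      double pr = 1.0 / (1.0 + std::exp(-e));
      if (pr < 1e-7) pr = 1e-7;
      if (pr > 1.0 - 1e-7) pr = 1.0 - 1e-7;
      double wi = pr * (1.0 - pr);
      if (wi < 1e-7) wi = 1e-7;
      w[i] = wi;
      z[i] = e + (y[i] - pr) / wi;
      r[i] = z[i] - e; // working residual at current coefficients
    }
    double wsum = 0.0;
    for (int i = 0; i < n; ++i) wsum += w[i];
    std::vector<double> v(p);
    for (int j = 0; j < p; ++j) {
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += w[i] * X(i, j) * X(i, j);
      v[j] = s / n;
    }
    const double tol_in = tol;
    std::vector<char> active(p, 1);
    double outer_change = 0.0;
    int it = 0;
    while (it < max_inner) {
      // sweep restricted to the active set, with a full sweep whenever the
      // restricted problem has converged; stop when the full sweep moves
      // nothing and activates no new coordinate
      bool full = true;
      double inner_change;
      do {
        inner_change = 0.0;
        ++it;
        double num0 = 0.0;
        for (int i = 0; i < n; ++i) num0 += w[i] * r[i];
        double d0 = num0 / wsum;
        if (d0 != 0.0) {
          b0 += d0;
          for (int i = 0; i < n; ++i) r[i] -= d0;
          inner_change = std::max(inner_change, std::fabs(d0));
        }
        for (int j = 0; j < p; ++j) {
          if (!full && !active[j]) continue;
          if (v[j] <= 0.0) continue; // constant column
          double num = 0.0;
          for (int i = 0; i < n; ++i) num += w[i] * X(i, j) * r[i];
          num = num / n + v[j] * beta[j];
          double bnew = penalty[j] ? soft(num, lambda) / v[j] : num / v[j];
          double d = bnew - beta[j];
          if (d != 0.0) {
            beta[j] = bnew;
            for (int i = 0; i < n; ++i) r[i] -= X(i, j) * d;
            inner_change = std::max(inner_change, std::fabs(d));
          }
          if (full) active[j] = (beta[j] != 0.0 || !penalty[j]);
        }
        outer_change = std::max(outer_change, inner_change);
        full = false;
      } while (inner_change >= tol_in && it < max_inner);
      // verification full sweep
      double check_change = 0.0;
      ++it;
      for (int j = 0; j < p; ++j) {
        if (v[j] <= 0.0) continue;
        double num = 0.0;
        for (int i = 0; i < n; ++i) num += w[i] * X(i, j) * r[i];
        num = num / n + v[j] * beta[j];
        double bnew = penalty[j] ? soft(num, lambda) / v[j] : num / v[j];
        double d = bnew - beta[j];
        if (d != 0.0) {
          beta[j] = bnew;
          for (int i = 0; i < n; ++i) r[i] -= X(i, j) * d;
          check_change = std::max(check_change, std::fabs(d));
        }
        active[j] = (beta[j] != 0.0 || !penalty[j]);
      }
      outer_change = std::max(outer_change, check_change);
      if (check_change < tol_in) break;
    }
    if (outer_change < tol) { converged = true; break; }
  }
  return List::create(_["beta"] = beta, _["intercept"] = b0,
                      _["iterations"] = outer + 1,
                      _["converged"] = converged);
}
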