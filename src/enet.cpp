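#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Penalized logistic regression along a lambda path.
//
// Minimizes  -(1/n) loglik(b0, beta)
//            + lambda * sum_j pf_j * ( alpha*|beta_j| + (1-alpha)/2 beta_j^2 )
// by IRLS outer loops with cyclic coordinate descent on the weighted
// quadratic approximation, warm-started along a decreasing lambda sequence.
// X is used as supplied (standardization is the caller's concern).

static inline double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// [[Rcpp::export(name = ".enet_logistic_path")]]
List enet_logistic_path(NumericMatrix X, NumericVector y, double alpha,
                        NumericVector lambdas, NumericVector pf,
                        double tol = 1e-7, int max_sweeps = 10000) {
  const int n = X.nrow(), p = X.ncol(), L = lambdas.size();
  const double *xp = REAL(X);           // column-major
  const double *yp = REAL(y);
  NumericMatrix betas(p, L);
  NumericVector b0s(L);
  IntegerVector sweeps_used(L);
  LogicalVector converged(L, true);

  std::vector<double> beta(p, 0.0);
  double b0 = 0.0;
  std::vector<double> eta(n), w(n), res(n);
  std::vector<bool> active(p, false);

  for (int l = 0; l < L; ++l) {
    const double lam = lambdas[l];
    int sweeps = 0;
    bool ok = false;
    for (int irls = 0; irls < 50 && !ok; ++irls) {
      // quadratic approximation at current (b0, beta)
      for (int i = 0; i < n; ++i) eta[i] = b0;
      for (int j = 0; j < p; ++j) {
        const double bj = beta[j];
        if (bj == 0.0) continue;
        const double *xj = xp + (size_t)j * n;
        for (int i = 0; i < n; ++i) eta[i] += xj[i] * bj;
      }
      double wsum = 0.0;
      for (int i = 0; i < n; ++i) {
        double pr = 1.0 / (1.0 + std::exp(-eta[i]));
        if (pr < 1e-5) pr = 1e-5;
        if (pr > 1.0 - 1e-5) pr = 1.0 - 1e-5;
        w[i] = pr * (1.0 - pr);
        wsum += w[i];
        // working residual z - eta, with z = eta + (y - pr) / w
        res[i] = (yp[i] - pr) / w[i];
      }

      // coordinate descent on the weighted least squares problem
      double max_change_outer = 0.0;
      bool full_pass = true;
      for (;;) {
        double max_change = 0.0;
        for (int j = 0; j < p; ++j) {
          if (!full_pass && !active[j]) continue;
          const double *xj = xp + (size_t)j * n;
          double num = 0.0, denom = 0.0;
          for (int i = 0; i < n; ++i) {
            const double wx = w[i] * xj[i];
            num += wx * res[i];
            denom += wx * xj[i];
          }
          num = num / n + denom / n * beta[j];
          denom /= n;
          const double bj = soft(num, lam * alpha * pf[j]) /
                            (denom + lam * (1.0 - alpha) * pf[j]);
          const double d = bj - beta[j];
          if (d != 0.0) {
            for (int i = 0; i < n; ++i) res[i] -= xj[i] * d;
            beta[j] = bj;
            const double ad = std::fabs(d);
            if (ad > max_change) max_change = ad;
          }
          active[j] = beta[j] != 0.0;
        }
        // intercept (unpenalized)
        {
          double num = 0.0;
          for (int i = 0; i < n; ++i) num += w[i] * res[i];
          const double d = num / wsum;
          if (d != 0.0) {
            for (int i = 0; i < n; ++i) res[i] -= d;
            b0 += d;
            const double ad = std::fabs(d);
            if (ad > max_change) max_change = ad;
          }
        }
        ++sweeps;
        if (max_change > max_change_outer) max_change_outer = max_change;
        if (sweeps >= max_sweeps) break;
        if (max_change < tol) {
          if (full_pass) break;       // converged on a full sweep
          full_pass = true;           // verify with one full sweep
        } else {
          full_pass = false;          // iterate the active set
        }
      }
      ok = (max_change_outer < tol) || sweeps >= max_sweeps;
      if (sweeps >= max_sweeps) { converged[l] = false; break; }
    }
    sweeps_used[l] = sweeps;
    for (int j = 0; j < p; ++j) betas(j, l) = beta[j];
    b0s[l] = b0;
  }
  return List::create(_["beta"] = betas, _["intercept"] = b0s,
                      _["sweeps"] = sweeps_used, _["converged"] = converged);
}
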