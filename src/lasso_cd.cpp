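#include <Rcpp.h>
using namespace Rcpp;

// Coordinate descent for the lasso objective
//   RSS(beta) + lambda * sum_j |beta_j|
// (no 1/n scaling). Soft-threshold update:
//   beta_j <- S(x_j'(r + x_j beta_j), lambda/2) / (x_j'x_j)
// Residuals are updated in place; exact zeros are preserved. After each
// full sweep the currently-active (non-zero) coordinates are iterated to
// convergence before the next full sweep (glmnet-style active set), which
// keeps the path cheap at small penalties. An iteration counts one sweep
// over a coordinate set.
// [[Rcpp::export(name = ".lasso_cd_path")]]
List lasso_cd_path(NumericMatrix X, NumericVector y, NumericVector lambdas,
                   double tol, int max_iter, NumericVector beta_init) {
  const int n = X.nrow(), p = X.ncol(), L = lambdas.size();
  const double *xp = X.begin();
  std::vector<double> col_ss(p);
  for (int j = 0; j < p; ++j) {
    const double *xj = xp + (size_t)j * n;
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += xj[i] * xj[i];
    col_ss[j] = s;
  }
  NumericMatrix betas(p, L);
  IntegerVector iters(L);
  LogicalVector conv(L);
  std::vector<double> beta(beta_init.begin(), beta_init.end());
  std::vector<double> r(n);
  for (int i = 0; i < n; ++i) r[i] = y[i];
  for (int j = 0; j < p; ++j) {
    if (beta[j] != 0.0) {
      const double *xj = xp + (size_t)j * n;
      for (int i = 0; i < n; ++i) r[i] -= xj[i] * beta[j];
    }
  }
  std::vector<int> active;
  active.reserve(p);

  for (int l = 0; l < L; ++l) {
    const double thr = lambdas[l] / 2.0;
    int it = 0;
    bool converged = false;
    while (it < max_iter) {
      // full sweep
      double max_delta = 0.0;
      for (int j = 0; j < p; ++j) {
        if (col_ss[j] <= 0.0) continue;
        const double *xj = xp + (size_t)j * n;
        double cj = 0.0;
        for (int i = 0; i < n; ++i) cj += xj[i] * r[i];
        cj += col_ss[j] * beta[j];
        double bj = 0.0;
        if (cj > thr) bj = (cj - thr) / col_ss[j];
        else if (cj < -thr) bj = (cj + thr) / col_ss[j];
        const double delta = bj - beta[j];
        if (delta != 0.0) {
          for (int i = 0; i < n; ++i) r[i] -= xj[i] * delta;
          beta[j] = bj;
          const double ad = std::fabs(delta);
          if (ad > max_delta) max_delta = ad;
        }
      }
      ++it;
      if (max_delta < tol) { converged = true; break; }
      // active-set sweeps until stable
      active.clear();
      for (int j = 0; j < p; ++j) if (beta[j] != 0.0) active.push_back(j);
      while (it < max_iter) {
        double md = 0.0;
        for (size_t a = 0; a < active.size(); ++a) {
          const int j = active[a];
          const double *xj = xp + (size_t)j * n;
          double cj = 0.0;
          for (int i = 0; i < n; ++i) cj += xj[i] * r[i];
          cj += col_ss[j] * beta[j];
          double bj = 0.0;
          if (cj > thr) bj = (cj - thr) / col_ss[j];
          else if (cj < -thr) bj = (cj + thr) / col_ss[j];
          const double delta = bj - beta[j];
          if (delta != 0.0) {
            for (int i = 0; i < n; ++i) r[i] -= xj[i] * delta;
            beta[j] = bj;
            const double ad = std::fabs(delta);
            if (ad > md) md = ad;
          }
        }
        ++it;
        if (md < tol) break;
      }
    }
    iters[l] = it;
    conv[l] = converged;
    for (int j = 0; j < p; ++j) betas(j, l) = beta[j];
  }
  return List::create(_["beta"] = betas, _["iter"] = iters,
                      _["converged"] = conv);
}
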