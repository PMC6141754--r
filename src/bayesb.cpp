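#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for spike-and-slab whole-genome regression (BayesB):
// each marker effect is zero with probability 1 - pi_in or drawn from a
// normal slab whose per-marker variance has a scaled-inverse-chi-square
// prior (the scaled-t slab after integration). Returns posterior means
// of the intercept, marker effects and inclusion indicators.
// [[Rcpp::export(name = ".bayesb_gibbs")]]
List bayesb_gibbs(const NumericMatrix& X, const NumericVector& y,
                  int n_iter, int burn_in, int thin,
                  double pi_in, double nu, double s2_beta,
                  double nu_e, double s2_e, bool update_pi) {
  const int n = X.nrow(), p = X.ncol();
  NumericVector beta(p), var_beta(p, s2_beta);
  LogicalVector inc(p, false);
  NumericVector e = clone(y);
  double mu = mean(y);
  for (int i = 0; i < n; ++i) e[i] -= mu;
  double sigma2_e = var(y) * 0.5;
  if (sigma2_e <= 0) sigma2_e = 1e-6;
  double pi_cur = pi_in;

  std::vector<double> xtx(p);
  for (int j = 0; j < p; ++j) {
    double s = 0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    xtx[j] = s;
  }

  NumericVector beta_sum(p), inc_sum(p);
  double mu_sum = 0;
  int n_kept = 0;

  for (int it = 0; it < n_iter; ++it) {
    // intercept
    double e_mean = mean(e);
    double mu_new = R::rnorm(mu + e_mean, std::sqrt(sigma2_e / n));
    double shift = mu_new - mu;
    for (int i = 0; i < n; ++i) e[i] -= shift;
    mu = mu_new;

    // marker effects
    for (int j = 0; j < p; ++j) {
      if (xtx[j] <= 0) continue;
      double rhs = 0;
      for (int i = 0; i < n; ++i) rhs += X(i, j) * e[i];
      rhs += xtx[j] * beta[j];
      // log marginal odds of inclusion given var_beta[j]
      double c = xtx[j] / sigma2_e;
      double v1 = 1.0 / (c + 1.0 / var_beta[j]);
      double m1 = v1 * rhs / sigma2_e;
      double log_bf = 0.5 * std::log(v1 / var_beta[j]) +
        0.5 * m1 * m1 / v1;
      double log_odds = std::log(pi_cur / (1 - pi_cur)) + log_bf;
      double pr = 1.0 / (1.0 + std::exp(-log_odds));
      double old = beta[j];
      if (R::unif_rand() < pr) {
        double b = R::rnorm(m1, std::sqrt(v1));
        beta[j] = b;
        inc[j] = true;
      } else {
        beta[j] = 0.0;
        inc[j] = false;
      }
      double d = beta[j] - old;
      if (d != 0.0)
        for (int i = 0; i < n; ++i) e[i] -= X(i, j) * d;
      // slab variance update (only informative when included)
      double b2 = inc[j] ? beta[j] * beta[j] : 0.0;
      double df = nu + (inc[j] ? 1.0 : 0.0);
      double sc = nu * s2_beta + b2;
      var_beta[j] = sc / R::rchisq(df);
      if (!R_finite(var_beta[j]) || var_beta[j] <= 1e-10)
        var_beta[j] = s2_beta;
    }

    // residual variance
    double sse = 0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    sigma2_e = (sse + nu_e * s2_e) / R::rchisq(n + nu_e);
    if (!R_finite(sigma2_e) || sigma2_e <= 1e-12)
      stop("divergent chain at iteration %d", it + 1);

    if (update_pi) {
      int k = sum(inc);
      pi_cur = R::rbeta(1.0 + k, 1.0 + p - k);
      pi_cur = std::min(std::max(pi_cur, 1e-4), 1.0 - 1e-4);
    }

    if (it >= burn_in && ((it - burn_in) % thin == 0)) {
      ++n_kept;
      mu_sum += mu;
      for (int j = 0; j < p; ++j) {
        beta_sum[j] += beta[j];
        if (inc[j]) inc_sum[j] += 1.0;
      }
    }
  }
  if (n_kept == 0) stop("no kept samples: check burn_in/thin");
  for (int j = 0; j < p; ++j) {
    beta_sum[j] /= n_kept;
    inc_sum[j] /= n_kept;
  }
  return List::create(_["mu"] = mu_sum / n_kept,
                      _["beta"] = beta_sum,
                      _["inclusion_prob"] = inc_sum,
                      _["n_kept"] = n_kept);
}
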