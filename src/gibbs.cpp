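#include <Rcpp.h>
using namespace Rcpp;

// Inverse-Gaussian draw (Michael, Schucany & Haas); used for 1/tau_j^2 in
// the Bayesian LASSO full conditional.
static double rinvgauss(double mu, double lambda) {
  double nu = R::norm_rand();
  double y = nu * nu;
  double x = mu + (mu * mu * y) / (2.0 * lambda) -
    (mu / (2.0 * lambda)) *
      std::sqrt(4.0 * mu * lambda * y + mu * mu * y * y);
  if (x <= 0.0) x = 1e-12;
  double u = R::unif_rand();
  if (u <= mu / (mu + x)) return x;
  return mu * mu / x;
}

// Gibbs sampler for whole-genome regression y = mu + X a + e.
// model "brr":    a_j ~ N(0, sigma2_m), sigma2_m ~ scaled-inv-chi2(df_a, S_a)
// model "blasso": a_j ~ N(0, tau2_j sigma2_e), 1/tau2_j inverse-Gaussian,
//                 lambda2 ~ Gamma(shape, rate) updated from its full
//                 conditional (Park-Casella).
// Residual sigma2_e ~ scaled-inv-chi2(df_e, S_e) in both models (for the
// LASSO the effect sum of squares enters its full conditional).
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export(name = ".gibbs_wgr")]]
List gibbs_wgr(NumericVector y, NumericMatrix X, std::string model,
               int n_iter, int burn_in, int thin,
               double df_a, double S_a, double df_e, double S_e,
               double lambda_shape, double lambda_rate,
               bool store_effects) {
  const int n = y.size();
  const int p = X.ncol();
  const bool lasso = (model == "blasso");

  std::vector<double> xx(p);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    xx[j] = s;
  }

  double vy = 0.0, my = 0.0;
  for (int i = 0; i < n; ++i) my += y[i];
  my /= n;
  for (int i = 0; i < n; ++i) vy += (y[i] - my) * (y[i] - my);
  vy /= std::max(n - 1, 1);
  if (vy <= 0.0) vy = 1e-8;

  double mu = my;
  std::vector<double> a(p, 0.0), tau2(p, 1.0);
  double sigma2_e = 0.5 * vy;
  double sigma2_m = 0.5 * vy / std::max(1, p);
  double lambda2 = 2.0 * p;  // heuristic start; overwritten by its update

  std::vector<double> e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;

  const int n_keep = (n_iter - burn_in) / thin;
  NumericVector mu_chain(n_keep), s2e_chain(n_keep), s2m_chain(n_keep),
      lam_chain(n_keep);
  NumericVector a_mean(p), a_m2(p), tau2_mean(p);
  NumericMatrix a_samples(store_effects ? n_keep : 0, store_effects ? p : 0);
  int kept = 0;

  for (int it = 0; it < n_iter; ++it) {
    // intercept
    double em = 0.0;
    for (int i = 0; i < n; ++i) em += e[i];
    em = em / n + mu;
    double mu_new = em + R::norm_rand() * std::sqrt(sigma2_e / n);
    double dmu = mu - mu_new;
    for (int i = 0; i < n; ++i) e[i] += dmu;
    mu = mu_new;

    // marker effects
    for (int j = 0; j < p; ++j) {
      if (xx[j] <= 0.0) { a[j] = 0.0; continue; }  // monomorphic: fixed at 0
      double vj = lasso ? (tau2[j] * sigma2_e) : sigma2_m;
      double rhs = xx[j] * a[j];
      for (int i = 0; i < n; ++i) rhs += X(i, j) * e[i];
      double C = xx[j] + sigma2_e / vj;
      double mean = rhs / C;
      double a_new = mean + R::norm_rand() * std::sqrt(sigma2_e / C);
      double d = a[j] - a_new;
      if (d != 0.0) for (int i = 0; i < n; ++i) e[i] += X(i, j) * d;
      a[j] = a_new;
    }

    double ssa = 0.0;  // sum a^2 (brr) or sum a^2 / tau2 (blasso)
    if (lasso) {
      double sum_tau2 = 0.0;
      for (int j = 0; j < p; ++j) {
        if (xx[j] <= 0.0) { tau2[j] = 1e-8; continue; }
        double aj2 = a[j] * a[j];
        if (aj2 < 1e-14) aj2 = 1e-14;
        double mu_ig = std::sqrt(lambda2 * sigma2_e / aj2);
        if (mu_ig > 1e8) mu_ig = 1e8;
        double inv_t2 = rinvgauss(mu_ig, lambda2);
        tau2[j] = 1.0 / inv_t2;
        sum_tau2 += tau2[j];
        ssa += aj2 / tau2[j];
      }
      // lambda^2 | tau2 ~ Gamma(p + shape, sum tau2 / 2 + rate)
      lambda2 = R::rgamma(p + lambda_shape,
                          1.0 / (sum_tau2 / 2.0 + lambda_rate));
      if (lambda2 > 1e12) {
        stop("lambda2 diverging (> 1e12): check the Gamma prior on lambda2");
      }
      sigma2_e = 0.0;
      double sse = 0.0;
      for (int i = 0; i < n; ++i) sse += e[i] * e[i];
      sigma2_e = (sse + ssa + S_e) / R::rchisq(n + p + df_e);
    } else {
      for (int j = 0; j < p; ++j) ssa += a[j] * a[j];
      sigma2_m = (ssa + S_a) / R::rchisq(p + df_a);
      double sse = 0.0;
      for (int i = 0; i < n; ++i) sse += e[i] * e[i];
      sigma2_e = (sse + S_e) / R::rchisq(n + df_e);
    }

    if (it >= burn_in && ((it - burn_in) % thin) == 0 && kept < n_keep) {
      mu_chain[kept] = mu;
      s2e_chain[kept] = sigma2_e;
      s2m_chain[kept] = sigma2_m;
      lam_chain[kept] = lambda2;
      for (int j = 0; j < p; ++j) {
        a_mean[j] += a[j];
        a_m2[j] += a[j] * a[j];
        tau2_mean[j] += tau2[j];
        if (store_effects) a_samples(kept, j) = a[j];
      }
      ++kept;
    }
  }
  for (int j = 0; j < p; ++j) {
    a_mean[j] /= std::max(kept, 1);
    a_m2[j] = a_m2[j] / std::max(kept, 1) - a_mean[j] * a_mean[j];
    tau2_mean[j] /= std::max(kept, 1);
  }
  double mu_mean = 0.0;
  for (int k2 = 0; k2 < kept; ++k2) mu_mean += mu_chain[k2];
  mu_mean /= std::max(kept, 1);
  return List::create(
      _["mu"] = mu_mean, _["mu_chain"] = mu_chain,
      _["effects"] = a_mean, _["effects_var"] = a_m2,
      _["sigma2_e_chain"] = s2e_chain, _["sigma2_m_chain"] = s2m_chain,
      _["lambda2_chain"] = lam_chain, _["tau2"] = tau2_mean,
      _["n_kept"] = kept, _["samples"] = a_samples);
}
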