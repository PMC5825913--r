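#include <Rcpp.h>
using namespace Rcpp;

// Scaled-inverse-chi-square draw: (df * scale) / chisq(df)
static double rscaled_inv_chisq(double df, double scale) {
  return df * scale / R::rchisq(df);
}

// Inverse-Gaussian draw (Michael, Schucany & Haas 1976)
static double rinvgauss(double mu, double lambda) {
  double v = R::rnorm(0.0, 1.0);
  double y = v * v;
  double x = mu + (mu * mu * y) / (2.0 * lambda) -
    (mu / (2.0 * lambda)) *
    std::sqrt(4.0 * mu * lambda * y + mu * mu * y * y);
  if (x <= 0.0) x = 1e-12;
  double u = R::runif(0.0, 1.0);
  if (u <= mu / (mu + x)) return x;
  return mu * mu / x;
}

// Common per-iteration coordinate update of marker effects with Gaussian
// full conditionals. resid is maintained as y - mu - X beta.
static void update_betas(const NumericMatrix& X, NumericVector& beta,
                         NumericVector& resid, const NumericVector& xtx,
                         double sigma2, const NumericVector& prior_var) {
  int n = X.nrow(), m = X.ncol();
  for (int j = 0; j < m; ++j) {
    double bj = beta[j];
    double xr = 0.0;
    for (int i = 0; i < n; ++i) xr += X(i, j) * resid[i];
    xr += xtx[j] * bj;              // X_j' (resid + X_j beta_j)
    double prec = xtx[j] / sigma2 + 1.0 / prior_var[j];
    double mean = (xr / sigma2) / prec;
    double newb = mean + R::rnorm(0.0, 1.0) / std::sqrt(prec);
    double d = newb - bj;
    if (d != 0.0) {
      for (int i = 0; i < n; ++i) resid[i] -= X(i, j) * d;
      beta[j] = newb;
    }
  }
}

// Bayesian ridge regression Gibbs sampler.
// Model: y = mu + X beta + e; beta_j ~ N(0, sigma2_beta) common variance;
// scaled-inv-chisq priors on sigma2_beta (df_b, S_b) and sigma2 (df_e, S_e).
// fix_sigma2 / fix_sigma2_beta > 0 freeze the respective variance.
// [[Rcpp::export]]
List gibbs_brr_cpp(NumericVector y, NumericMatrix X,
                   int n_iter, int burn_in, int thin,
                   double df_b, double S_b, double df_e, double S_e,
                   double fix_sigma2, double fix_sigma2_beta) {
  int n = y.size(), m = X.ncol();
  NumericVector beta(m, 0.0), resid = clone(y);
  double mu = mean(y);
  for (int i = 0; i < n; ++i) resid[i] -= mu;
  NumericVector xtx(m);
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    xtx[j] = (s > 1e-12) ? s : 1e-12;
  }
  double sigma2 = (fix_sigma2 > 0) ? fix_sigma2 : var(y) * 0.5;
  double sigma2_b = (fix_sigma2_beta > 0) ? fix_sigma2_beta
                                          : var(y) * 0.5 / m;
  int n_keep = (n_iter - burn_in) / thin;
  NumericMatrix beta_samp(n_keep, m);
  NumericVector mu_samp(n_keep), s2_samp(n_keep), s2b_samp(n_keep);
  NumericVector prior_var(m);
  int keep = 0;
  for (int it = 0; it < n_iter; ++it) {
    // mu | rest
    double rsum = 0.0;
    for (int i = 0; i < n; ++i) rsum += resid[i] + mu;
    double mu_new = R::rnorm(rsum / n, std::sqrt(sigma2 / n));
    for (int i = 0; i < n; ++i) resid[i] -= (mu_new - mu);
    mu = mu_new;
    // beta | rest
    std::fill(prior_var.begin(), prior_var.end(), sigma2_b);
    update_betas(X, beta, resid, xtx, sigma2, prior_var);
    // sigma2_beta | beta
    if (fix_sigma2_beta <= 0) {
      double ssb = 0.0;
      for (int j = 0; j < m; ++j) ssb += beta[j] * beta[j];
      sigma2_b = rscaled_inv_chisq(df_b + m, (ssb + df_b * S_b) / (df_b + m));
    }
    // sigma2 | resid
    if (fix_sigma2 <= 0) {
      double rss = 0.0;
      for (int i = 0; i < n; ++i) rss += resid[i] * resid[i];
      sigma2 = rscaled_inv_chisq(df_e + n, (rss + df_e * S_e) / (df_e + n));
    }
    if (!R_finite(sigma2) || !R_finite(sigma2_b))
      stop("non-finite variance draw at iteration %d", it + 1);
    if (it >= burn_in && (it - burn_in) % thin == 0 && keep < n_keep) {
      beta_samp(keep, _) = beta;
      mu_samp[keep] = mu;
      s2_samp[keep] = sigma2;
      s2b_samp[keep] = sigma2_b;
      ++keep;
    }
  }
  return List::create(_["beta"] = beta_samp, _["mu"] = mu_samp,
                      _["sigma2"] = s2_samp, _["sigma2_beta"] = s2b_samp);
}

// Bayesian LASSO Gibbs sampler (Park & Casella parameterisation).
// beta_j | tau2_j, sigma2 ~ N(0, tau2_j * sigma2);
// tau2_j ~ Exp(rate = lambda2 / 2); lambda2 ~ Gamma(shape_l, rate_l);
// sigma2 ~ scaled-inv-chisq(df_e, S_e).
// fix_lambda2 > 0 freezes lambda2; fix_tau2 > 0 freezes all tau2_j at that
// value (degenerate equal-variance setting, for validation against ridge).
// [[Rcpp::export]]
List gibbs_bl_cpp(NumericVector y, NumericMatrix X,
                  int n_iter, int burn_in, int thin,
                  double shape_l, double rate_l,
                  double df_e, double S_e,
                  double fix_lambda2, double fix_tau2) {
  int n = y.size(), m = X.ncol();
  NumericVector beta(m, 0.0), resid = clone(y), tau2(m, 0.01);
  double mu = mean(y);
  for (int i = 0; i < n; ++i) resid[i] -= mu;
  NumericVector xtx(m);
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    xtx[j] = (s > 1e-12) ? s : 1e-12;
  }
  double sigma2 = var(y) * 0.5;
  double lambda2 = (fix_lambda2 > 0) ? fix_lambda2 : 1.0;
  if (fix_tau2 > 0) std::fill(tau2.begin(), tau2.end(), fix_tau2);
  int n_keep = (n_iter - burn_in) / thin;
  NumericMatrix beta_samp(n_keep, m);
  NumericVector mu_samp(n_keep), s2_samp(n_keep), l2_samp(n_keep);
  NumericVector prior_var(m);
  int keep = 0;
  for (int it = 0; it < n_iter; ++it) {
    double rsum = 0.0;
    for (int i = 0; i < n; ++i) rsum += resid[i] + mu;
    double mu_new = R::rnorm(rsum / n, std::sqrt(sigma2 / n));
    for (int i = 0; i < n; ++i) resid[i] -= (mu_new - mu);
    mu = mu_new;
    for (int j = 0; j < m; ++j) prior_var[j] = tau2[j] * sigma2;
    update_betas(X, beta, resid, xtx, sigma2, prior_var);
    if (fix_tau2 <= 0) {
      for (int j = 0; j < m; ++j) {
        double b2 = beta[j] * beta[j];
        if (b2 < 1e-14) b2 = 1e-14;
        double inv_tau2 = rinvgauss(std::sqrt(lambda2 * sigma2 / b2),
                                    lambda2);
        tau2[j] = 1.0 / inv_tau2;
      }
      if (fix_lambda2 <= 0) {
        double st = 0.0;
        for (int j = 0; j < m; ++j) st += tau2[j];
        lambda2 = R::rgamma(shape_l + m, 1.0 / (rate_l + st / 2.0));
      }
    }
    double rss = 0.0, pen = 0.0;
    for (int i = 0; i < n; ++i) rss += resid[i] * resid[i];
    for (int j = 0; j < m; ++j) pen += beta[j] * beta[j] / tau2[j];
    sigma2 = rscaled_inv_chisq(df_e + n + m,
                               (rss + pen + df_e * S_e) / (df_e + n + m));
    if (!R_finite(sigma2) || !R_finite(lambda2))
      stop("non-finite variance draw at iteration %d", it + 1);
    if (it >= burn_in && (it - burn_in) % thin == 0 && keep < n_keep) {
      beta_samp(keep, _) = beta;
      mu_samp[keep] = mu;
      s2_samp[keep] = sigma2;
      l2_samp[keep] = lambda2;
      ++keep;
    }
  }
  return List::create(_["beta"] = beta_samp, _["mu"] = mu_samp,
                      _["sigma2"] = s2_samp, _["lambda2"] = l2_samp);
}
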