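#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Draw from a standard normal truncated to (a, Inf). Inverse-CDF works in the
// body of the distribution; for truncation points deep in the upper tail it
// loses precision, so switch to Robert's (1995) translated-exponential
// rejection sampler there.
static double rtnorm_above(double a) {
  if (a < 0.45) {
    double p = R::pnorm(a, 0.0, 1.0, 1, 0);
    double q = p + R::unif_rand() * (1.0 - p);
    if (q >= 1.0) q = 1.0 - 1e-16;
    if (q <= 0.0) q = 1e-16;
    return R::qnorm(q, 0.0, 1.0, 1, 0);
  }
  double lambda = 0.5 * (a + std::sqrt(a * a + 4.0));
  for (;;) {
    double x = a - std::log(R::unif_rand()) / lambda;
    double d = x - lambda;
    if (std::log(R::unif_rand()) <= -0.5 * d * d) return x;
  }
}

//' Albert-Chib data-augmentation Gibbs sampler for binary probit regression.
//'
//' Latent z_i ~ N(x_i' beta, 1) truncated by the observed class; beta gets a
//' diffuse N(0, prior_var * I) prior. Latent variance is fixed at 1. Uses R's
//' RNG so results are reproducible under set.seed().
// [[Rcpp::export(name = ".gibbs_probit_cpp")]]
arma::mat gibbs_probit_cpp(const arma::mat& X, const arma::ivec& y,
                           int iterations, int burn_in, double prior_var) {
  const int n = X.n_rows, p = X.n_cols;
  arma::mat prec = X.t() * X + arma::eye(p, p) / prior_var;
  arma::mat B = arma::inv_sympd(prec);
  arma::mat L = arma::chol(B, "lower");
  arma::mat XtB = B * X.t();  // p x n, posterior mean of beta is XtB * z

  arma::vec beta(p, arma::fill::zeros);
  arma::vec z(n);
  const int kept = iterations - burn_in;
  arma::mat draws(kept, p);

  Rcpp::RNGScope scope;
  for (int it = 0; it < iterations; ++it) {
    arma::vec mu = X * beta;
    for (int i = 0; i < n; ++i) {
      if (y[i] == 1)
        z[i] = mu[i] + rtnorm_above(-mu[i]);   // z_i > 0
      else
        z[i] = mu[i] - rtnorm_above(mu[i]);    // z_i < 0
    }
    arma::vec m = XtB * z;
    arma::vec eps(p);
    for (int j = 0; j < p; ++j) eps[j] = R::norm_rand();
    beta = m + L * eps;
    if (it >= burn_in) draws.row(it - burn_in) = beta.t();
  }
  return draws;
}
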