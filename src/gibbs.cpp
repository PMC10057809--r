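// Gibbs samplers for the per-equation coefficient posteriors.
// Uses R's RNG (via Rcpp sugar / R API) so a set.seed() on the R side makes
// every chain exactly reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Inverse-Gaussian sampler (Michael, Schucany & Haas 1976).
static double rinvgauss1(double mu, double lambda) {
  double nu = norm_rand();
  double y = nu * nu;
  double x = mu + (mu * mu * y) / (2.0 * lambda) -
             (mu / (2.0 * lambda)) *
                 std::sqrt(4.0 * mu * lambda * y + mu * mu * y * y);
  if (x <= 0.0) x = 1e-12;
  double z = unif_rand();
  if (z <= mu / (mu + x)) return x;
  return mu * mu / x;
}

// Draw beta ~ N(A^{-1} Xty, sigma2 A^{-1}) with A = XtX + Dinv.
static arma::vec draw_beta(const arma::mat& XtX, const arma::vec& Xty,
                           const arma::vec& dinv, double sigma2) {
  arma::uword p = XtX.n_cols;
  arma::mat A = XtX;
  A.diag() += dinv;
  arma::mat L = arma::chol(arma::symmatu(A), "lower");
  arma::vec m = arma::solve(arma::trimatu(L.t()),
                            arma::solve(arma::trimatl(L), Xty));
  arma::vec z(p);
  for (arma::uword j = 0; j < p; ++j) z(j) = norm_rand();
  arma::vec dev = arma::solve(arma::trimatu(L.t()), z);
  return m + std::sqrt(sigma2) * dev;
}

// Bayesian Lasso (Park & Casella 2008): Laplace prior as a normal scale
// mixture with per-coefficient latent scales tau2, inverse-gamma noise
// variance, gamma hyperprior on lambda^2.
// [[Rcpp::export]]
List blasso_gibbs_cpp(const arma::vec& y, const arma::mat& X,
                      int iterations, int burn_in, int thinning,
                      double a0 = 0.001, double b0 = 0.001,
                      double r = 1.0, double delta = 0.1) {
  const arma::uword n = X.n_rows, p = X.n_cols;
  arma::mat XtX = X.t() * X;
  arma::vec Xty = X.t() * y;

  // start at ridge solution
  arma::mat A0 = XtX;
  A0.diag() += 1.0;
  arma::vec beta = arma::solve(arma::symmatu(A0), Xty);
  double sigma2 = arma::as_scalar(arma::mean(arma::square(y - X * beta)));
  if (sigma2 <= 0) sigma2 = 1e-6;
  arma::vec tau2(p, arma::fill::ones);
  double lambda2 = 1.0;

  const int n_keep = (iterations - burn_in) / thinning;
  arma::mat keep_beta(n_keep, p);
  arma::vec keep_sigma2(n_keep), keep_lambda2(n_keep);

  int stored = 0;
  for (int it = 0; it < iterations; ++it) {
    // beta | tau2, sigma2
    beta = draw_beta(XtX, Xty, 1.0 / tau2, sigma2);

    // 1/tau2_j | beta, sigma2, lambda2  ~ InvGauss
    for (arma::uword j = 0; j < p; ++j) {
      double bj2 = beta(j) * beta(j);
      if (bj2 < 1e-12) bj2 = 1e-12;
      double mu = std::sqrt(lambda2 * sigma2 / bj2);
      double inv = rinvgauss1(mu, lambda2);
      tau2(j) = 1.0 / inv;
    }

    // sigma2 | beta, tau2
    arma::vec resid = y - X * beta;
    double shape = a0 + 0.5 * (double)(n + p);
    double rate = b0 + 0.5 * arma::dot(resid, resid) +
                  0.5 * arma::dot(arma::square(beta), 1.0 / tau2);
    sigma2 = rate / R::rgamma(shape, 1.0);
    if (sigma2 <= 0 || !std::isfinite(sigma2)) sigma2 = 1e-10;

    // lambda2 | tau2
    lambda2 = R::rgamma((double)p + r, 1.0 / (delta + 0.5 * arma::accu(tau2)));
    if (lambda2 <= 0 || !std::isfinite(lambda2)) lambda2 = 1e-10;

    if (it >= burn_in && (it - burn_in) % thinning == 0 && stored < n_keep) {
      keep_beta.row(stored) = beta.t();
      keep_sigma2(stored) = sigma2;
      keep_lambda2(stored) = lambda2;
      ++stored;
    }
  }
  return List::create(_["beta"] = keep_beta, _["sigma2"] = keep_sigma2,
                      _["lambda2"] = keep_lambda2);
}

// Semiconjugate baseline: beta ~ N(0, I / prior_precision) independent of
// sigma2 ~ IG(a0, b0); Gibbs between the two conditionals.
// [[Rcpp::export]]
List semiconj_gibbs_cpp(const arma::vec& y, const arma::mat& X,
                        double prior_precision, int iterations, int burn_in,
                        int thinning, double a0 = 0.001, double b0 = 0.001) {
  const arma::uword n = X.n_rows, p = X.n_cols;
  arma::mat XtX = X.t() * X;
  arma::vec Xty = X.t() * y;

  arma::mat A0 = XtX;
  A0.diag() += prior_precision + 1e-8;
  arma::vec beta = arma::solve(arma::symmatu(A0), Xty);
  double sigma2 = arma::as_scalar(arma::mean(arma::square(y - X * beta)));
  if (sigma2 <= 0) sigma2 = 1e-6;

  const int n_keep = (iterations - burn_in) / thinning;
  arma::mat keep_beta(n_keep, p);
  arma::vec keep_sigma2(n_keep);

  int stored = 0;
  for (int it = 0; it < iterations; ++it) {
    // beta | sigma2: N(S Xty/sigma2, S), S = (XtX/sigma2 + prec I)^{-1}
    arma::mat A = XtX / sigma2;
    A.diag() += prior_precision;
    arma::mat L = arma::chol(arma::symmatu(A), "lower");
    arma::vec m = arma::solve(arma::trimatu(L.t()),
                              arma::solve(arma::trimatl(L), Xty / sigma2));
    arma::vec z(p);
    for (arma::uword j = 0; j < p; ++j) z(j) = norm_rand();
    beta = m + arma::solve(arma::trimatu(L.t()), z);

    // sigma2 | beta
    arma::vec resid = y - X * beta;
    double shape = a0 + 0.5 * (double)n;
    double rate = b0 + 0.5 * arma::dot(resid, resid);
    sigma2 = rate / R::rgamma(shape, 1.0);
    if (sigma2 <= 0 || !std::isfinite(sigma2)) sigma2 = 1e-10;

    if (it >= burn_in && (it - burn_in) % thinning == 0 && stored < n_keep) {
      keep_beta.row(stored) = beta.t();
      keep_sigma2(stored) = sigma2;
      ++stored;
    }
  }
  return List::create(_["beta"] = keep_beta, _["sigma2"] = keep_sigma2);
}
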