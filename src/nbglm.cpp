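// Negative-binomial GLM machinery shared by the paired DE stage.
//
// Model: y ~ NB(mu, phi), log mu = X beta + offset, variance mu + phi mu^2.
// Fitting is Fisher-scoring IRLS with step halving on the log-likelihood;
// dispersion estimation uses the Cox-Reid adjusted profile likelihood
// evaluated on a fixed log2-spaced grid.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double MU_MIN = 1e-10;
static const double MU_MAX = 1e12;

// NB log-likelihood at mean vector mu (phi > 0). Terms in y are skipped for
// y == 0 so that the mu -> 0 limit is handled exactly (ll -> 0 per sample).
static double nb_ll(const arma::vec& y, const arma::vec& mu, double phi) {
  const double inv = 1.0 / phi;
  double ll = 0.0;
  for (arma::uword i = 0; i < y.n_elem; ++i) {
    double m = std::min(std::max(mu[i], MU_MIN), MU_MAX);
    ll += -inv * std::log1p(phi * m);
    if (y[i] > 0.0) {
      ll += R::lgammafn(y[i] + inv) - R::lgammafn(inv) - R::lgammafn(y[i] + 1.0)
          + y[i] * (std::log(phi * m) - std::log1p(phi * m));
    }
  }
  return ll;
}

// IRLS with step halving for one gene. Returns convergence flag; fills beta
// and ll at the optimum.
static bool fit_one(const arma::vec& y, const arma::mat& X, const arma::vec& off,
                    double phi, arma::vec& beta, double& ll,
                    int maxit = 100, double tol = 1e-8) {
  const arma::uword n = y.n_elem;

  // initialise from least squares on shifted-log counts
  arma::vec z0 = arma::log(y + 0.5) - off;
  if (!arma::solve(beta, X, z0)) beta = arma::pinv(X) * z0;

  arma::vec eta = X * beta + off;
  arma::vec mu = arma::clamp(arma::exp(eta), MU_MIN, MU_MAX);
  ll = nb_ll(y, mu, phi);
  bool conv = false;

  for (int it = 0; it < maxit; ++it) {
    arma::vec w = mu / (1.0 + phi * mu);       // Fisher weights, log link
    arma::vec z = (eta - off) + (y - mu) / mu; // working response
    arma::mat Xw = X.each_col() % w;
    arma::mat XtWX = X.t() * Xw;
    arma::vec XtWz = Xw.t() * z;

    arma::vec bnew;
    if (!arma::solve(bnew, XtWX, XtWz, arma::solve_opts::likely_sympd)) {
      bnew = arma::pinv(XtWX) * XtWz;
    }
    arma::vec delta = bnew - beta;

    double step = 1.0, llnew = ll;
    arma::vec btry = beta, etat = eta, mut = mu;
    int h = 0;
    for (; h < 30; ++h) {
      btry = beta + step * delta;
      etat = X * btry + off;
      mut = arma::clamp(arma::exp(etat), MU_MIN, MU_MAX);
      llnew = nb_ll(y, mut, phi);
      if (std::isfinite(llnew) &&
          llnew >= ll - 1e-12 * (1.0 + std::abs(ll))) break;
      step *= 0.5;
    }
    if (h == 30) { conv = true; break; }  // no uphill step exists: at optimum
    double dll = llnew - ll;
    beta = btry; eta = etat; mu = mut; ll = llnew;
    if (std::abs(dll) < tol) { conv = true; break; }
    (void) n;
  }
  return conv;
}

//' @noRd
// [[Rcpp::export(name = ".cxx_nb_fit")]]
List cxx_nb_fit(const arma::mat& Y, const arma::mat& X,
                const arma::vec& offset, const arma::vec& phi) {
  const arma::uword G = Y.n_rows, p = X.n_cols;
  arma::mat coef(G, p, arma::fill::zeros);
  arma::vec ll(G);
  LogicalVector conv(G);
  for (arma::uword g = 0; g < G; ++g) {
    arma::vec beta(p);
    double l = 0.0;
    bool ok = fit_one(Y.row(g).t(), X, offset, phi[g], beta, l);
    coef.row(g) = beta.t();
    ll[g] = l;
    conv[g] = ok;
  }
  return List::create(_["coefficients"] = coef,
                      _["loglik"] = ll,
                      _["converged"] = conv);
}

//' @noRd
// [[Rcpp::export(name = ".cxx_nb_apl")]]
arma::mat cxx_nb_apl(const arma::mat& Y, const arma::mat& X,
                     const arma::vec& offset, const arma::vec& phi_grid) {
  const arma::uword G = Y.n_rows, K = phi_grid.n_elem, p = X.n_cols;
  arma::mat apl(G, K);
  for (arma::uword g = 0; g < G; ++g) {
    arma::vec y = Y.row(g).t();
    for (arma::uword k = 0; k < K; ++k) {
      double phi = phi_grid[k];
      arma::vec beta(p);
      double ll = 0.0;
      fit_one(y, X, offset, phi, beta, ll);
      arma::vec mu = arma::clamp(arma::exp(X * beta + offset), MU_MIN, MU_MAX);
      arma::vec w = mu / (1.0 + phi * mu);
      arma::mat XtWX = X.t() * (X.each_col() % w);
      // Cox-Reid adjustment: -1/2 log det(X' W X); ridge keeps the
      // determinant finite for all-zero genes where W -> 0
      XtWX.diag() += 1e-12;
      double val, sign;
      arma::log_det(val, sign, XtWX);
      apl(g, k) = ll - 0.5 * val;
    }
  }
  return apl;
}
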