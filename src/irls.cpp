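#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Maximum-likelihood logistic regression by iteratively reweighted least
// squares. Convergence on relative deviance change; quasi-complete
// separation is flagged (not corrected) when any |beta| exceeds `betaCap`
// or the deviance fails to stabilise within `maxit` iterations.
namespace {

const double BETA_CAP = 15.0;

struct IrlsFit {
  arma::vec beta;
  arma::vec se;
  double deviance;
  int iterations;
  bool converged;   // IRLS stabilised
  bool estimable;   // normal equations solvable (design full rank)
  bool separated;   // |beta| > cap => unreliable estimates
};

double binomial_deviance(const arma::vec& y, const arma::vec& mu) {
  double dev = 0.0;
  for (arma::uword i = 0; i < y.n_elem; ++i) {
    double m = std::min(std::max(mu[i], 1e-300), 1.0 - 1e-16);
    dev += y[i] > 0.5 ? -2.0 * std::log(m) : -2.0 * std::log1p(-m);
  }
  return dev;
}

IrlsFit irls(const arma::mat& X, const arma::vec& y, int maxit, double tol) {
  const arma::uword p = X.n_cols;
  IrlsFit fit;
  fit.beta.zeros(p);
  fit.se.set_size(p);
  fit.se.fill(NA_REAL);
  fit.deviance = NA_REAL;
  fit.iterations = 0;
  fit.converged = false;
  fit.estimable = true;
  fit.separated = false;

  double dev_old = std::numeric_limits<double>::infinity();
  arma::mat H(p, p);
  for (int it = 1; it <= maxit; ++it) {
    fit.iterations = it;
    arma::vec eta = X * fit.beta;
    arma::vec mu = 1.0 / (1.0 + arma::exp(-eta));
    arma::vec w = mu % (1.0 - mu);
    w.transform([](double v) { return v < 1e-10 ? 1e-10 : v; });
    arma::vec z = eta + (y - mu) / w;
    arma::mat Xw = X;
    Xw.each_col() %= w;
    H = X.t() * Xw;
    arma::vec rhs = Xw.t() * z;
    arma::vec bnew;
    if (!arma::solve(bnew, H, rhs, arma::solve_opts::no_approx)) {
      fit.estimable = false;
      fit.beta.fill(NA_REAL);
      return fit;
    }
    fit.beta = bnew;
    arma::vec mu2 = 1.0 / (1.0 + arma::exp(-(X * fit.beta)));
    double dev = binomial_deviance(y, mu2);
    fit.deviance = dev;
    if (std::fabs(dev - dev_old) < tol * (std::fabs(dev) + 0.1)) {
      fit.converged = true;
      break;
    }
    dev_old = dev;
  }

  // Observed information at the final estimate
  arma::vec mu = 1.0 / (1.0 + arma::exp(-(X * fit.beta)));
  arma::vec w = mu % (1.0 - mu);
  arma::mat Xw = X;
  Xw.each_col() %= w;
  H = X.t() * Xw;
  arma::mat V;
  if (arma::inv_sympd(V, H) || arma::inv(V, H)) {
    fit.se = arma::sqrt(V.diag());
  } else {
    fit.estimable = false;
  }
  if (!fit.beta.is_finite() || arma::abs(fit.beta).max() > BETA_CAP) {
    fit.separated = true;
  }
  return fit;
}

}  // namespace

//' Logistic regression IRLS fit (internal)
//'
//' @param X design matrix (n x p), including the intercept column.
//' @param y 0/1 response of length n.
//' @param maxit maximum IRLS iterations.
//' @param tol relative deviance-change convergence tolerance.
//' @return list with elements beta, se, deviance, iterations, converged,
//'   estimable, separated.
//' @keywords internal
// [[Rcpp::export(name = ".Call_logisticIrls")]]
List logisticIrlsCpp(const arma::mat& X, const arma::vec& y,
                     int maxit = 25, double tol = 1e-8) {
  IrlsFit fit = irls(X, y, maxit, tol);
  return List::create(
      _["beta"] = NumericVector(fit.beta.begin(), fit.beta.end()),
      _["se"] = NumericVector(fit.se.begin(), fit.se.end()),
      _["deviance"] = fit.deviance,
      _["iterations"] = fit.iterations,
      _["converged"] = fit.converged && fit.estimable && !fit.separated,
      _["estimable"] = fit.estimable,
      _["separated"] = fit.separated);
}

//' Per-variant logistic interaction scan (internal)
//'
//' Fits outcome ~ intercept + g + e + g:e + covariates for every row of the
//' dosage matrix. Samples with missing dosage are dropped per variant
//' (complete-case); y, e and the covariate matrix must already be complete.
//'
//' @param G variants x samples dosage matrix; NA marks missing calls.
//' @param y 0/1 outcome per sample.
//' @param E exposure per sample.
//' @param C samples x k covariate matrix (k may be 0).
//' @return variants x 8 matrix: beta_int, se_int, beta_g, beta_e, se_g,
//'   se_e, n_used, converged (1/0).
//' @keywords internal
// [[Rcpp::export(name = ".Call_gwisScan")]]
NumericMatrix gwisScanCpp(const NumericMatrix& G, const arma::vec& y,
                          const arma::vec& E, const arma::mat& C,
                          int maxit = 25, double tol = 1e-8) {
  const int m = G.nrow();
  const int n = G.ncol();
  const int k = C.n_cols;
  const int p = 4 + k;
  NumericMatrix out(m, 8);
  colnames(out) = CharacterVector::create("beta_int", "se_int", "beta_g",
                                          "beta_e", "se_g", "se_e", "n_used",
                                          "converged");

  arma::mat X(n, p);
  arma::vec yy(n);
  for (int j = 0; j < m; ++j) {
    int nu = 0;
    bool seen0 = false, seen1 = false;
    for (int i = 0; i < n; ++i) {
      double g = G(j, i);
      if (NumericMatrix::is_na(g)) continue;
      X(nu, 0) = 1.0;
      X(nu, 1) = g;
      X(nu, 2) = E[i];
      X(nu, 3) = g * E[i];
      for (int c = 0; c < k; ++c) X(nu, 4 + c) = C(i, c);
      yy[nu] = y[i];
      if (y[i] > 0.5) seen1 = true; else seen0 = true;
      ++nu;
    }
    out(j, 6) = nu;
    if (nu < p || !seen0 || !seen1) {
      for (int c = 0; c < 6; ++c) out(j, c) = NA_REAL;
      out(j, 7) = 0.0;
      continue;
    }
    IrlsFit fit = irls(X.head_rows(nu), yy.head(nu), maxit, tol);
    bool ok = fit.converged && fit.estimable && !fit.separated;
    out(j, 0) = fit.beta[3];
    out(j, 1) = fit.se[3];
    out(j, 2) = fit.beta[1];
    out(j, 3) = fit.beta[2];
    out(j, 4) = fit.se[1];
    out(j, 5) = fit.se[2];
    out(j, 7) = ok ? 1.0 : 0.0;
  }
  return out;
}
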