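// Negative binomial GLM kernel: per-gene IRLS with log link and fixed
// dispersion, NB deviance/log-likelihood, and the Cox-Reid adjustment
// 0.5*logdet(X'WX) used by adjusted-profile-likelihood dispersion
// estimation. Genes share one design and one offset vector; dispersion
// varies per gene.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double ETA_MAX = 50.0;
static const double MU_MIN = 1e-10;

static double nb_unit_deviance_sum(const vec &y, const vec &mu, double phi) {
  double dev = 0.0;
  const unsigned n = y.n_elem;
  if (phi > 0.0) {
    const double r = 1.0 / phi;
    for (unsigned i = 0; i < n; ++i) {
      double mui = std::max(mu[i], MU_MIN);
      double a = (y[i] > 0.0) ? y[i] * std::log(y[i] / mui) : 0.0;
      dev += 2.0 * (a - (y[i] + r) * std::log((y[i] + r) / (mui + r)));
    }
  } else {
    for (unsigned i = 0; i < n; ++i) {
      double mui = std::max(mu[i], MU_MIN);
      double a = (y[i] > 0.0) ? y[i] * std::log(y[i] / mui) : 0.0;
      dev += 2.0 * (a - (y[i] - mui));
    }
  }
  return dev;
}

static double nb_loglik_sum(const vec &y, const vec &mu, double phi) {
  double ll = 0.0;
  const unsigned n = y.n_elem;
  if (phi > 0.0) {
    const double r = 1.0 / phi;
    for (unsigned i = 0; i < n; ++i) {
      double mui = std::max(mu[i], MU_MIN);
      ll += std::lgamma(y[i] + r) - std::lgamma(r) - std::lgamma(y[i] + 1.0) +
            r * std::log(r / (r + mui)) + y[i] * std::log(mui / (r + mui));
    }
  } else {
    for (unsigned i = 0; i < n; ++i) {
      double mui = std::max(mu[i], MU_MIN);
      ll += y[i] * std::log(mui) - mui - std::lgamma(y[i] + 1.0);
    }
  }
  return ll;
}

// one IRLS step: given eta (linear predictor incl. offset), solve WLS
static bool wls_solve(const mat &X, const vec &y, const vec &off,
                      const vec &eta, double phi, vec &beta_out) {
  vec mu = exp(eta);
  mu.transform([](double m) { return std::max(m, MU_MIN); });
  vec w = mu / (1.0 + phi * mu);
  vec z = (eta - off) + (y - mu) / mu;
  mat Xw = X.each_col() % w;
  mat A = X.t() * Xw;
  vec b = Xw.t() * z;
  return solve(beta_out, A, b, solve_opts::likely_sympd + solve_opts::no_approx);
}

// Fit one gene; returns convergence flag. beta/mu/dev/iters are outputs.
static bool nb_irls_one(const vec &y, const mat &X, const vec &off, double phi,
                        double tol, int maxit, vec &beta, vec &mu, double &dev,
                        int &iters) {
  const unsigned p = X.n_cols;
  // initialise from shifted log counts
  vec mu0 = y + 0.125;
  vec eta0 = log(mu0);
  beta.set_size(p);
  if (!wls_solve(X, y, off, eta0, phi, beta)) {
    // fall back to least squares on log scale
    beta = solve(X, eta0 - off);
  }
  vec eta = clamp(X * beta + off, -ETA_MAX, ETA_MAX);
  mu = exp(eta);
  dev = nb_unit_deviance_sum(y, mu, phi);
  bool conv = false;
  iters = 0;
  for (int it = 1; it <= maxit; ++it) {
    iters = it;
    vec beta_new(p);
    if (!wls_solve(X, y, off, eta, phi, beta_new)) break;
    vec eta_new = clamp(X * beta_new + off, -ETA_MAX, ETA_MAX);
    vec mu_new = exp(eta_new);
    double dev_new = nb_unit_deviance_sum(y, mu_new, phi);
    // step halving if the deviance did not improve
    int half = 0;
    while ((!std::isfinite(dev_new) || dev_new > dev + 1e-10) && half < 8) {
      beta_new = 0.5 * (beta_new + beta);
      eta_new = clamp(X * beta_new + off, -ETA_MAX, ETA_MAX);
      mu_new = exp(eta_new);
      dev_new = nb_unit_deviance_sum(y, mu_new, phi);
      ++half;
    }
    double delta = std::fabs(dev - dev_new) / (std::fabs(dev_new) + 0.1);
    beta = beta_new;
    eta = eta_new;
    mu = mu_new;
    dev = dev_new;
    if (delta < tol) {
      conv = true;
      break;
    }
  }
  return conv;
}

static double cox_reid_adj(const mat &X, const vec &mu, double phi) {
  vec w = mu / (1.0 + phi * mu);
  w.transform([](double v) { return std::max(v, 1e-12); });
  mat A = X.t() * (X.each_col() % w);
  double val, sign;
  log_det(val, sign, A);
  return 0.5 * val;
}

//' @noRd
// [[Rcpp::export(name = ".nb_fit_genes_cpp")]]
Rcpp::List nb_fit_genes_cpp(const arma::mat &Y, const arma::mat &X,
                            const arma::vec &offset, const arma::vec &phi,
                            double tol, int maxit, bool want_apl,
                            bool want_mu) {
  const unsigned G = Y.n_rows, n = Y.n_cols, p = X.n_cols;
  mat coef(G, p, fill::value(datum::nan));
  mat Mu;
  if (want_mu) Mu.set_size(G, n);
  vec dev(G, fill::zeros), apl(G, fill::value(datum::nan));
  Rcpp::IntegerVector iters(G);
  Rcpp::LogicalVector converged(G), degenerate(G);
  vec beta(p), mu(n);
  for (unsigned g = 0; g < G; ++g) {
    vec y = Y.row(g).t();
    if (accu(y) <= 0.0) {
      degenerate[g] = true;
      converged[g] = true;
      dev[g] = 0.0;
      if (want_mu) Mu.row(g).zeros();
      continue;
    }
    double d;
    int it;
    bool conv = nb_irls_one(y, X, offset, phi[g], tol, maxit, beta, mu, d, it);
    coef.row(g) = beta.t();
    dev[g] = d;
    iters[g] = it;
    converged[g] = conv;
    if (want_mu) Mu.row(g) = mu.t();
    if (want_apl)
      apl[g] = nb_loglik_sum(y, mu, phi[g]) - cox_reid_adj(X, mu, phi[g]);
  }
  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("coefficients") = coef, Rcpp::Named("deviance") = dev,
      Rcpp::Named("iter") = iters, Rcpp::Named("converged") = converged,
      Rcpp::Named("degenerate") = degenerate);
  if (want_apl) out["apl"] = apl;
  if (want_mu) out["fitted"] = Mu;
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".nb_deviance_cpp")]]
arma::vec nb_deviance_cpp(const arma::mat &Y, const arma::mat &Mu,
                          const arma::vec &phi) {
  const unsigned G = Y.n_rows;
  vec out(G);
  for (unsigned g = 0; g < G; ++g) {
    vec y = Y.row(g).t();
    vec mu = Mu.row(g).t();
    out[g] = nb_unit_deviance_sum(y, mu, phi[g]);
  }
  return out;
}

// unscaled covariance factor: per-gene c' (X'WX)^{-1} c for each contrast
//' @noRd
// [[Rcpp::export(name = ".contrast_unscaled_var_cpp")]]
arma::mat contrast_unscaled_var_cpp(const arma::mat &Mu, const arma::mat &X,
                                    const arma::vec &phi,
                                    const arma::mat &Cmat) {
  const unsigned G = Mu.n_rows, q = Cmat.n_cols;
  mat out(G, q);
  for (unsigned g = 0; g < G; ++g) {
    vec mu = Mu.row(g).t();
    mu.transform([](double v) { return std::max(v, MU_MIN); });
    vec w = mu / (1.0 + phi[g] * mu);
    mat A = X.t() * (X.each_col() % w);
    mat Ainv;
    if (!inv_sympd(Ainv, A)) Ainv = pinv(A);
    for (unsigned j = 0; j < q; ++j) {
      out(g, j) = as_scalar(Cmat.col(j).t() * Ainv * Cmat.col(j));
    }
  }
  return out;
}
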