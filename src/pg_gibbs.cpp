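// Polya-Gamma augmented Gibbs sampler for the two-level logistic model
//   logit P(y_i = 1) = x_i' beta + u_{j(i)},  u_j ~ N(0, sigma2)
// PG(1, z) draws use Devroye's alternating-series rejection sampler
// (truncation point t = 0.64) with R's RNG, so R-side set.seed() governs
// reproducibility.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

static const double TRUNC = 0.64;

// coefficients a_n(x) of the Jacobi-type alternating series, piecewise in x
static double a_coef(int n, double x) {
  double nph = n + 0.5;
  if (x <= TRUNC) {
    return M_PI * nph *
      std::exp(1.5 * (std::log(2.0 / M_PI) - std::log(x)) - 2.0 * nph * nph / x);
  }
  return M_PI * nph * std::exp(-0.5 * nph * nph * M_PI * M_PI * x);
}

// inverse-Gaussian(mu, lambda = 1) sampler (Michael-Schucany-Haas)
static double rinvgauss1(double mu) {
  double y = R::norm_rand();
  y = y * y;
  double muy = mu * y;
  double x = mu + 0.5 * mu * (muy - std::sqrt(4.0 * muy + muy * muy));
  if (R::unif_rand() > mu / (mu + x)) x = mu * mu / x;
  return x;
}

// inverse-Gaussian(1/z, 1) truncated to (0, t); Devroye / Windle scheme
static double rtinvgauss(double z, double t) {
  double x = t + 1.0;
  if (1.0 / z > t) {
    // small z: sample via X = t/(1 + t E)^2 with squeeze, accept w.p. exp(-z^2 x / 2)
    double alpha = 0.0;
    while (R::unif_rand() > alpha) {
      double e1, e2;
      do {
        e1 = R::exp_rand();
        e2 = R::exp_rand();
      } while (e1 * e1 > 2.0 * e2 / t);
      x = t / ((1.0 + t * e1) * (1.0 + t * e1));
      alpha = std::exp(-0.5 * z * z * x);
    }
  } else {
    double mu = 1.0 / z;
    while (x >= t) x = rinvgauss1(mu);
  }
  return x;
}

// CDF of inverse-Gaussian(1/z, 1) at t, used for the proposal mixing weight
static double pigauss(double t, double z) {
  double rt = 1.0 / std::sqrt(t);
  return R::pnorm(rt * (t * z - 1.0), 0.0, 1.0, 1, 0) +
         std::exp(2.0 * z) * R::pnorm(-rt * (t * z + 1.0), 0.0, 1.0, 1, 0);
}

// single PG(1, z) draw: 0.25 * J*(1, z/2)
static double rpg1(double z) {
  z = 0.5 * std::fabs(z);
  double K = M_PI * M_PI / 8.0 + 0.5 * z * z;
  // proposal masses: exponential tail (x > t) vs truncated inverse-Gaussian (x <= t)
  double q = M_PI / (2.0 * K) * std::exp(-K * TRUNC);
  double p = 2.0 * std::exp(-z) * pigauss(TRUNC, z);
  double ratio = p / (p + q);
  for (;;) {
    double x;
    if (R::unif_rand() < ratio) {
      x = rtinvgauss(z, TRUNC);
    } else {
      x = TRUNC + R::exp_rand() / K;
    }
    // alternating-series accept/reject
    double s = a_coef(0, x);
    double y = R::unif_rand() * s;
    int n = 0;
    for (;;) {
      ++n;
      if (n % 2 == 1) {
        s -= a_coef(n, x);
        if (y <= s) return 0.25 * x;
      } else {
        s += a_coef(n, x);
        if (y > s) break;
      }
    }
  }
}

//' @noRd
// [[Rcpp::export(rng = true, name = ".rpg")]]
Rcpp::NumericVector rpg(int n, Rcpp::NumericVector z) {
  Rcpp::NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rpg1(z[i % z.size()]);
  return out;
}

static double rinvgamma(double shape, double scale) {
  return scale / R::rgamma(shape, 1.0);
}

//' Gibbs sampler core; called per chain from fit_mcmc()
//'
//' sigma_prior: 0 = half-Cauchy(0, sigma_scale) on sigma_u via
//' parameter-expanded inverse-gamma mixture; 1 = InvGamma(ig_shape, ig_rate)
//' on sigma2; 2 = sigma2 fixed at sigma2_fixed (no update, u drawn with that
//' variance; sigma2_fixed = 0 pins all u_j at zero).
//' @noRd
// [[Rcpp::export(rng = true, name = ".gibbs_logit_mixed")]]
Rcpp::List gibbs_logit_mixed(const arma::vec& y,
                             const arma::mat& X,
                             const arma::uvec& group,  // 0-based LSOA index
                             int n_groups,
                             int n_burn, int n_iter, int thin,
                             double beta_prior_var,
                             int sigma_prior,
                             double sigma_scale,
                             double ig_shape, double ig_rate,
                             double sigma2_fixed) {
  const int n = X.n_rows, p = X.n_cols, J = n_groups;
  arma::vec kappa = y - 0.5;
  arma::vec beta(p, arma::fill::zeros);
  arma::vec u(J, arma::fill::zeros);
  double sigma2 = (sigma_prior == 2) ? sigma2_fixed : 0.25;
  double a_aux = 1.0;  // PX latent for the half-Cauchy mixture

  int n_keep = n_iter / thin;
  arma::mat beta_out(n_keep, p);
  arma::mat u_out(n_keep, J);
  arma::vec sigma2_out(n_keep);

  arma::vec psi(n), omega(n), ugrp(n);
  arma::mat P(p, p);
  int keep = 0;

  for (int it = 0; it < n_burn + n_iter; ++it) {
    // 1. Polya-Gamma latent variables
    for (int i = 0; i < n; ++i) ugrp[i] = u[group[i]];
    psi = X * beta + ugrp;
    for (int i = 0; i < n; ++i) omega[i] = rpg1(psi[i]);

    // 2. fixed effects: beta | omega, u ~ N(m, V)
    arma::mat Xw = X.each_col() % arma::sqrt(omega);
    P = Xw.t() * Xw;
    P.diag() += 1.0 / beta_prior_var;
    arma::vec b = X.t() * (kappa - omega % ugrp);
    arma::mat L = arma::chol(P, "lower");
    arma::vec m = arma::solve(arma::trimatu(L.t()),
                              arma::solve(arma::trimatl(L), b));
    arma::vec zdraw(p);
    for (int k = 0; k < p; ++k) zdraw[k] = R::norm_rand();
    beta = m + arma::solve(arma::trimatu(L.t()), zdraw);

    // 3. random intercepts, conditionally independent given beta
    if (sigma_prior == 2 && sigma2_fixed <= 0.0) {
      u.zeros();
    } else {
      arma::vec xb = X * beta;
      arma::vec prec(J, arma::fill::value(1.0 / sigma2));
      arma::vec rsum(J, arma::fill::zeros);
      for (int i = 0; i < n; ++i) {
        prec[group[i]] += omega[i];
        rsum[group[i]] += kappa[i] - omega[i] * xb[i];
      }
      for (int j = 0; j < J; ++j)
        u[j] = rsum[j] / prec[j] + R::norm_rand() / std::sqrt(prec[j]);
    }

    // 4. between-group variance
    if (sigma_prior != 2) {
      double ssu = arma::dot(u, u);
      if (sigma_prior == 0) {
        sigma2 = rinvgamma(0.5 * (J + 1.0), 1.0 / a_aux + 0.5 * ssu);
        a_aux = rinvgamma(1.0, 1.0 / (sigma_scale * sigma_scale) + 1.0 / sigma2);
      } else {
        sigma2 = rinvgamma(ig_shape + 0.5 * J, ig_rate + 0.5 * ssu);
      }
    }

    if (it >= n_burn && (it - n_burn) % thin == 0) {
      beta_out.row(keep) = beta.t();
      u_out.row(keep) = u.t();
      sigma2_out[keep] = sigma2;
      ++keep;
    }
  }

  return Rcpp::List::create(Rcpp::Named("beta") = beta_out,
                            Rcpp::Named("u") = u_out,
                            Rcpp::Named("sigma2") = sigma2_out);
}
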