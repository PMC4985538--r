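// Metropolis-within-Gibbs kernels for the three Poisson log-linear models:
//   glm_chain        - no spatial structure (phi = 0)
//   leroux_chain     - Leroux CAR random effects (single-site MH for phi,
//                      conjugate inverse-gamma for tau2, logit-scale MH for rho)
//   orthogonal_chain - orthogonal smoothing: delta on a fixed eigenvector
//                      basis M with prior N(0, tau2 * Qs^-1)
// Proposal scales adapt only during burn-in, so retained draws come from a
// fixed-kernel Markov chain.  All log-densities carry their normalising
// constants: the per-draw loglik and logprior feed the marginal-likelihood
// average used for model weights, where constants matter.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static double pois_loglik(const arma::vec& Y, const arma::vec& logE,
                          const arma::vec& eta, const arma::vec& lgamY1) {
  // sum_i [ Y_i (logE_i + eta_i) - E_i exp(eta_i) - lgamma(Y_i + 1) ]
  return arma::accu(Y % (logE + eta) - arma::exp(logE + eta)) - arma::accu(lgamY1);
}

static double mvn_diag_logpdf(const arma::vec& x, const arma::vec& m,
                              const arma::vec& Vdiag) {
  const double ln2pi = std::log(2.0 * M_PI);
  arma::vec z = x - m;
  return -0.5 * arma::accu(arma::square(z) / Vdiag)
         - 0.5 * arma::accu(arma::log(Vdiag))
         - 0.5 * x.n_elem * ln2pi;
}

static double invgamma_logpdf(double x, double a, double b) {
  return a * std::log(b) - R::lgammafn(a) - (a + 1.0) * std::log(x) - b / x;
}

// Robbins-Monro style doubling/halving of a proposal scale, burn-in only.
static void adapt_scale(double& scale, int& acc, int& tries, double target) {
  if (tries >= 50) {
    double rate = (double)acc / tries;
    if (rate > target + 0.05) scale *= 1.2;
    else if (rate < target - 0.05) scale /= 1.2;
    acc = 0; tries = 0;
  }
}

// [[Rcpp::export]]
List glm_chain(const arma::vec& Y, const arma::vec& E, const arma::mat& Z,
               const arma::vec& m, const arma::vec& Vdiag,
               const arma::vec& beta0, const arma::vec& prop_se,
               int iterations, int burnin, int thin) {
  int n = Y.n_elem, p = Z.n_cols;
  int J = (iterations - burnin) / thin;
  arma::vec logE = arma::log(E);
  arma::vec lgamY1(n);
  for (int i = 0; i < n; ++i) lgamY1(i) = R::lgammafn(Y(i) + 1.0);

  arma::vec beta = beta0;
  arma::vec eta = Z * beta;
  double ll = pois_loglik(Y, logE, eta, lgamY1);
  if (!std::isfinite(ll)) stop("non-finite likelihood at initial values");
  double lp_beta = mvn_diag_logpdf(beta, m, Vdiag);

  double scale = 1.0;
  int acc = 0, tries = 0; long acc_total = 0, tries_total = 0;
  arma::mat beta_out(J, p);
  arma::vec ll_out(J), lprior_out(J);
  int save = 0;

  for (int it = 1; it <= iterations; ++it) {
    arma::vec prop = beta;
    for (int k = 0; k < p; ++k) prop(k) += scale * prop_se(k) * R::norm_rand();
    arma::vec eta_p = Z * prop;
    double ll_p = pois_loglik(Y, logE, eta_p, lgamY1);
    double lp_p = mvn_diag_logpdf(prop, m, Vdiag);
    if (std::isfinite(ll_p) &&
        std::log(R::unif_rand()) < (ll_p + lp_p) - (ll + lp_beta)) {
      beta = prop; eta = eta_p; ll = ll_p; lp_beta = lp_p;
      ++acc; ++acc_total;
    }
    ++tries; ++tries_total;
    if (it <= burnin) adapt_scale(scale, acc, tries, 0.4);
    if (it > burnin && (it - burnin) % thin == 0) {
      beta_out.row(save) = beta.t();
      ll_out(save) = ll;
      lprior_out(save) = lp_beta;
      ++save;
    }
  }
  return List::create(_["beta"] = beta_out, _["loglik"] = ll_out,
                      _["logprior"] = lprior_out,
                      _["accept_beta"] = (double)acc_total / tries_total,
                      _["scale_beta"] = scale);
}

// [[Rcpp::export]]
List leroux_chain(const arma::vec& Y, const arma::vec& E, const arma::mat& Z,
                  const arma::vec& m, const arma::vec& Vdiag,
                  double a, double b,
                  const arma::ivec& adj, const arma::ivec& adj_start,
                  const arma::vec& degree, const arma::ivec& edge_i,
                  const arma::ivec& edge_j, const arma::vec& lambda,
                  const arma::vec& beta0, const arma::vec& prop_se,
                  double rho0, double tau20,
                  int iterations, int burnin, int thin) {
  int n = Y.n_elem, p = Z.n_cols, nedge = edge_i.n_elem;
  int J = (iterations - burnin) / thin;
  const double ln2pi = std::log(2.0 * M_PI);
  arma::vec logE = arma::log(E);
  arma::vec lgamY1(n);
  for (int i = 0; i < n; ++i) lgamY1(i) = R::lgammafn(Y(i) + 1.0);

  arma::vec beta = beta0, phi(n, arma::fill::zeros);
  double rho = rho0, tau2 = tau20;
  arma::vec lin = Z * beta;               // covariate part of eta
  double ll = pois_loglik(Y, logE, lin + phi, lgamY1);
  if (!std::isfinite(ll)) stop("non-finite likelihood at initial values");

  auto logdetQ = [&](double r) {         // log det [r(D-W) + (1-r)I]
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += std::log(r * lambda(i) + 1.0 - r);
    return s;
  };
  auto quadform = [&](double r) {        // phi' [r(D-W)+(1-r)I] phi
    double se = 0.0;
    for (int e = 0; e < nedge; ++e) {
      double d = phi(edge_i(e)) - phi(edge_j(e));
      se += d * d;
    }
    return r * se + (1.0 - r) * arma::dot(phi, phi);
  };

  double scale_b = 1.0, scale_phi = 0.5, scale_rho = 0.5;
  int acc_b = 0, try_b = 0, acc_f = 0, try_f = 0, acc_r = 0, try_r = 0;
  long accT_b = 0, tryT_b = 0, accT_f = 0, tryT_f = 0, accT_r = 0, tryT_r = 0;

  arma::mat beta_out(J, p), phi_out(J, n);
  arma::vec rho_out(J), tau2_out(J), ll_out(J), lprior_out(J);
  int save = 0;

  for (int it = 1; it <= iterations; ++it) {
    // --- beta: joint random-walk MH ---
    {
      arma::vec prop = beta;
      for (int k = 0; k < p; ++k) prop(k) += scale_b * prop_se(k) * R::norm_rand();
      arma::vec lin_p = Z * prop;
      double ll_p = pois_loglik(Y, logE, lin_p + phi, lgamY1);
      double dpr = mvn_diag_logpdf(prop, m, Vdiag) - mvn_diag_logpdf(beta, m, Vdiag);
      if (std::isfinite(ll_p) && std::log(R::unif_rand()) < ll_p - ll + dpr) {
        beta = prop; lin = lin_p; ll = ll_p; ++acc_b; ++accT_b;
      }
      ++try_b; ++tryT_b;
    }
    // --- phi: single-site MH with Leroux full-conditional prior ---
    for (int i = 0; i < n; ++i) {
      double denom = rho * degree(i) + 1.0 - rho;
      double nbsum = 0.0;
      for (int k = adj_start(i); k < adj_start(i + 1); ++k) nbsum += phi(adj(k));
      double pm = rho * nbsum / denom;
      double pprec = denom / tau2;
      double cur = phi(i);
      double prop = cur + scale_phi * R::norm_rand();
      double dlik = Y(i) * (prop - cur)
                    - E(i) * (std::exp(lin(i) + prop) - std::exp(lin(i) + cur));
      double dpri = -0.5 * pprec * ((prop - pm) * (prop - pm) - (cur - pm) * (cur - pm));
      if (std::log(R::unif_rand()) < dlik + dpri) {
        phi(i) = prop; ++acc_f; ++accT_f;
      }
      ++try_f; ++tryT_f;
    }
    // centre phi for identifiability with the intercept
    phi -= arma::mean(phi);
    ll = pois_loglik(Y, logE, lin + phi, lgamY1);
    // --- tau2: conjugate inverse-gamma ---
    double quad = quadform(rho);
    tau2 = 1.0 / R::rgamma(a + 0.5 * n, 1.0 / (b + 0.5 * quad));
    // --- rho: random-walk MH on the logit scale (uniform(0,1) prior) ---
    {
      double theta = std::log(rho / (1.0 - rho));
      double theta_p = theta + scale_rho * R::norm_rand();
      double rho_p = 1.0 / (1.0 + std::exp(-theta_p));
      double quad_p = quadform(rho_p);
      double lacc = 0.5 * (logdetQ(rho_p) - logdetQ(rho))
                    - (quad_p - quad) / (2.0 * tau2)
                    + std::log(rho_p * (1.0 - rho_p)) - std::log(rho * (1.0 - rho));
      if (std::isfinite(lacc) && std::log(R::unif_rand()) < lacc) {
        rho = rho_p; quad = quad_p; ++acc_r; ++accT_r;
      }
      ++try_r; ++tryT_r;
    }
    if (it <= burnin) {
      adapt_scale(scale_b, acc_b, try_b, 0.4);
      adapt_scale(scale_phi, acc_f, try_f, 0.4);
      adapt_scale(scale_rho, acc_r, try_r, 0.4);
    }
    if (it > burnin && (it - burnin) % thin == 0) {
      beta_out.row(save) = beta.t();
      phi_out.row(save) = phi.t();
      rho_out(save) = rho; tau2_out(save) = tau2;
      ll_out(save) = ll;
      double lp = mvn_diag_logpdf(beta, m, Vdiag)
                  + 0.5 * logdetQ(rho) - 0.5 * n * (ln2pi + std::log(tau2))
                  - quad / (2.0 * tau2)
                  + invgamma_logpdf(tau2, a, b);   // rho ~ U(0,1): log 1 = 0
      lprior_out(save) = lp;
      ++save;
    }
  }
  return List::create(_["beta"] = beta_out, _["phi"] = phi_out,
                      _["rho"] = rho_out, _["tau2"] = tau2_out,
                      _["loglik"] = ll_out, _["logprior"] = lprior_out,
                      _["accept_beta"] = (double)accT_b / tryT_b,
                      _["accept_phi"] = (double)accT_f / tryT_f,
                      _["accept_rho"] = (double)accT_r / tryT_r);
}

// [[Rcpp::export]]
List orthogonal_chain(const arma::vec& Y, const arma::vec& E, const arma::mat& Z,
                      const arma::vec& m, const arma::vec& Vdiag,
                      double a, double b,
                      const arma::mat& M, const arma::mat& Qs, double logdetQs,
                      const arma::vec& beta0, const arma::vec& prop_se,
                      double tau20, int iterations, int burnin, int thin) {
  int n = Y.n_elem, p = Z.n_cols, q = M.n_cols;
  int J = (iterations - burnin) / thin;
  const double ln2pi = std::log(2.0 * M_PI);
  arma::vec logE = arma::log(E);
  arma::vec lgamY1(n);
  for (int i = 0; i < n; ++i) lgamY1(i) = R::lgammafn(Y(i) + 1.0);

  arma::vec beta = beta0, delta(q, arma::fill::zeros);
  double tau2 = tau20;
  arma::vec lin = Z * beta;
  arma::vec field(n, arma::fill::zeros);   // M * delta
  double ll = pois_loglik(Y, logE, lin + field, lgamY1);
  if (!std::isfinite(ll)) stop("non-finite likelihood at initial values");

  double scale_b = 1.0, scale_d = 0.5;
  int acc_b = 0, try_b = 0, acc_d = 0, try_d = 0;
  long accT_b = 0, tryT_b = 0, accT_d = 0, tryT_d = 0;

  arma::mat beta_out(J, p), delta_out(J, q);
  arma::vec tau2_out(J), ll_out(J), lprior_out(J);
  int save = 0;

  for (int it = 1; it <= iterations; ++it) {
    // --- beta ---
    {
      arma::vec prop = beta;
      for (int k = 0; k < p; ++k) prop(k) += scale_b * prop_se(k) * R::norm_rand();
      arma::vec lin_p = Z * prop;
      double ll_p = pois_loglik(Y, logE, lin_p + field, lgamY1);
      double dpr = mvn_diag_logpdf(prop, m, Vdiag) - mvn_diag_logpdf(beta, m, Vdiag);
      if (std::isfinite(ll_p) && std::log(R::unif_rand()) < ll_p - ll + dpr) {
        beta = prop; lin = lin_p; ll = ll_p; ++acc_b; ++accT_b;
      }
      ++try_b; ++tryT_b;
    }
    // --- delta: single-site MH; conditional prior from precision Qs/tau2 ---
    for (int jdx = 0; jdx < q; ++jdx) {
      double qjj = Qs(jdx, jdx);
      double dotj = arma::dot(Qs.col(jdx), delta) - qjj * delta(jdx);
      double pm = -dotj / qjj;
      double pprec = qjj / tau2;
      double cur = delta(jdx);
      double prop = cur + scale_d * R::norm_rand();
      double dd = prop - cur;
      arma::vec field_p = field + M.col(jdx) * dd;
      double ll_p = pois_loglik(Y, logE, lin + field_p, lgamY1);
      double dpri = -0.5 * pprec * ((prop - pm) * (prop - pm) - (cur - pm) * (cur - pm));
      if (std::isfinite(ll_p) && std::log(R::unif_rand()) < ll_p - ll + dpri) {
        delta(jdx) = prop; field = field_p; ll = ll_p; ++acc_d; ++accT_d;
      }
      ++try_d; ++tryT_d;
    }
    // --- tau2: conjugate inverse-gamma with the Qs quadratic form ---
    double quad = arma::as_scalar(delta.t() * Qs * delta);
    tau2 = 1.0 / R::rgamma(a + 0.5 * q, 1.0 / (b + 0.5 * quad));
    if (it <= burnin) {
      adapt_scale(scale_b, acc_b, try_b, 0.4);
      adapt_scale(scale_d, acc_d, try_d, 0.4);
    }
    if (it > burnin && (it - burnin) % thin == 0) {
      beta_out.row(save) = beta.t();
      delta_out.row(save) = delta.t();
      tau2_out(save) = tau2;
      ll_out(save) = ll;
      double lp = mvn_diag_logpdf(beta, m, Vdiag)
                  + 0.5 * logdetQs - 0.5 * q * (ln2pi + std::log(tau2))
                  - quad / (2.0 * tau2)
                  + invgamma_logpdf(tau2, a, b);
      lprior_out(save) = lp;
      ++save;
    }
  }
  return List::create(_["beta"] = beta_out, _["delta"] = delta_out,
                      _["tau2"] = tau2_out,
                      _["loglik"] = ll_out, _["logprior"] = lprior_out,
                      _["accept_beta"] = (double)accT_b / tryT_b,
                      _["accept_delta"] = (double)accT_d / tryT_d);
}
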