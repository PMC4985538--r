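test_that("design matrix has fixed column order and rejects collinearity", {
  Z <- build_design(c(1, 2), c(3, 4))
  expect_equal(unname(Z), rbind(c(1, 1, 3), c(1, 2, 4)))
  expect_equal(colnames(Z), c("intercept", "exposure", "deprivation"))
  expect_error(build_design(c(1, 2), c(3, 3)), "constant")
  expect_error(build_design(c(2, 2), c(3, 4)), "constant")

  g <- build_lattice_graph(8, 8)
  d <- sim_dataset(g, seed = 5)
  expect_equal(qr(d$Z)$rank, 3)
})

test_that("mcmc configuration enforces the bookkeeping invariants", {
  mc <- mcmc_config()
  expect_equal(retained_draws(mc), 50000)
  expect_equal(retained_draws(mcmc_config(3, 10000, 5000, 5)), 3000)
  expect_error(mcmc_config(iterations = 100, burnin = 200), "burnin")
  expect_error(mcmc_config(iterations = 1030, burnin = 1000, thin = 7),
               "divisible")
  expect_error(mcmc_config(thin = 0), "thin")
})

test_that("GLM sampler collapses to the prior when it dominates", {
  g <- build_lattice_graph(6, 6)
  d <- sim_dataset(g, seed = 2)
  f <- fit_glm(d$Y, d$E, d$Z, priors = prior_spec(m = 0, v = 1e-8),
               mcmc = quick_mcmc())
  expect_lt(max(abs(apply(f$beta, 2, stats::median))), 1e-3)
})

test_that("GLM posterior agrees with the IRLS maximum-likelihood oracle", {
  g <- build_lattice_graph(10, 10)
  d <- sim_dataset(g, rr = 1.05, tau2 = 1e-6, seed = 3)
  f <- fit_glm(d$Y, d$E, d$Z, mcmc = quick_mcmc(iterations = 6000, burnin = 2000))
  ml <- suppressWarnings(stats::glm.fit(d$Z, d$Y, offset = log(d$E),
                                        family = stats::poisson()))
  post_mean <- colMeans(f$beta)
  post_sd <- apply(f$beta, 2, stats::sd)
  expect_true(all(abs(post_mean - ml$coefficients) < 3 * post_sd))
})

test_that("Leroux tau2 full conditional has inverse-gamma shape a + n/2", {
  # prior-sampling oracle: for phi ~ Leroux(rho, tau2), the conditional
  # posterior mean of tau2 given phi is (b + quad/2)/(a + n/2 - 1);
  # averaging over prior draws of phi recovers tau2 (E[quad] = n tau2).
  g <- build_lattice_graph(8, 8)
  rho <- 0.6; tau2 <- 0.4; a <- 2; b <- 0.1
  Q1 <- leroux_precision(g, rho, 1)$Q        # precision at tau2 = 1
  R <- chol(Q1 / tau2)
  set.seed(8)
  quads <- replicate(4000, {
    phi <- backsolve(R, stats::rnorm(g$n))
    drop(crossprod(phi, Q1 %*% phi))
  })
  expect_equal(mean(quads) / g$n, tau2, tolerance = 0.02)
  cond_means <- (b + quads / 2) / (a + g$n / 2 - 1)
  expect_equal(mean(cond_means), tau2, tolerance = 0.02)
})

test_that("Leroux fit degenerates to the GLM when the field is forced to zero", {
  g <- build_lattice_graph(8, 8)
  d <- sim_dataset(g, tau2 = 1e-6, seed = 6)
  mc <- quick_mcmc(iterations = 4000, burnin = 2000)
  # prior forcing tau2 -> 0 pins phi at 0
  fl <- fit_leroux(d$Y, d$E, d$Z, g, priors = prior_spec(a = 1e5, b = 1e-3),
                   mcmc = mc)
  fg <- fit_glm(d$Y, d$E, d$Z, mcmc = mc)
  b_l <- apply(fl$beta, 2, stats::median)
  b_g <- apply(fg$beta, 2, stats::median)
  sd_g <- apply(fg$beta, 2, stats::sd)
  expect_true(all(abs(b_l - b_g) < 3 * sd_g))
  expect_lt(stats::median(fl$tau2), 1e-4)
})

test_that("orthogonal basis is covariate-orthogonal with descending positive eigenvalues", {
  g <- build_lattice_graph(5, 5)
  d <- sim_dataset(g, seed = 9)
  B <- build_orthogonal_basis(d$Z, g, q = 10)
  expect_lt(max(abs(crossprod(B$M, d$Z))), 1e-8)
  expect_lt(max(abs(crossprod(B$M) - diag(10))), 1e-8)
  expect_true(all(B$eigenvalues > 0))
  expect_true(all(diff(B$eigenvalues) <= 1e-12))
  # eigenpair residual against the projected adjacency (dense oracle)
  P <- d$Z %*% solve(crossprod(d$Z), t(d$Z))
  A <- (diag(g$n) - P) %*% g$W %*% (diag(g$n) - P)
  resid <- A %*% B$M - B$M %*% diag(B$eigenvalues)
  expect_lt(max(abs(resid)), 1e-8)
  expect_error(build_orthogonal_basis(d$Z, g, q = 26), "positive eigenvalues")
})

test_that("orthogonal fit recovers the effect when the field lies in the basis span", {
  g <- build_lattice_graph(12, 12)
  set.seed(14)
  x <- stats::rnorm(g$n, 18, 6)
  u <- stats::rnorm(g$n)
  Z <- build_design(x, u)
  E <- generate_population(g, seed = 15)$E
  B <- build_orthogonal_basis(Z, g, q = 20)
  delta <- stats::rnorm(20, 0, 0.3) * exp(-seq_len(20) / 8)
  b2 <- beta_for_rr(1.05)
  eta <- log(1.05) - b2 * 18 + b2 * x + 0.05 * u + drop(B$M %*% delta)
  Y <- stats::rpois(g$n, E * exp(eta))
  f <- fit_orthogonal(Y, E, Z, g, mcmc = quick_mcmc(iterations = 6000,
                                                    burnin = 3000), q = 20)
  s <- summarise_fit(f)
  expect_lt(abs(s$rr - 1.05), 0.03)
  expect_true(s$rr_lower <= 1.05 && s$rr_upper >= 1.05)
})

test_that("stored log-likelihoods match recomputation from stored draws", {
  g <- build_lattice_graph(6, 6)
  d <- sim_dataset(g, seed = 21)
  mc <- quick_mcmc(chains = 2, iterations = 1500, burnin = 500)
  for (f in list(fit_glm(d$Y, d$E, d$Z, mcmc = mc),
                 fit_leroux(d$Y, d$E, d$Z, g, mcmc = mc),
                 fit_orthogonal(d$Y, d$E, d$Z, g, mcmc = mc, q = 10))) {
    expect_equal(recompute_loglik(f, d$Y, d$E, d$Z), f$loglik,
                 tolerance = 1e-10)
  }
})

test_that("fits are reproducible and draws round-trip through CSV", {
  g <- build_lattice_graph(5, 5)
  d <- sim_dataset(g, seed = 23)
  mc <- quick_mcmc(chains = 2, iterations = 1200, burnin = 400)
  f1 <- fit_leroux(d$Y, d$E, d$Z, g, mcmc = mc)
  f2 <- fit_leroux(d$Y, d$E, d$Z, g, mcmc = mc)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$phi, f2$phi)

  stem <- file.path(withr::local_tempdir(), "fit")
  write_draws(f1, stem)
  back <- read_draws(stem)
  expect_equal(back$beta, f1$beta, ignore_attr = TRUE)
  expect_equal(back$loglik, f1$loglik)
  expect_equal(back$logprior, f1$logprior)
  expect_equal(back$model$structure, "leroux")
  expect_equal(log_marginal_likelihood(back), log_marginal_likelihood(f1))
})

test_that("chains mix on the default-style scenario (PSRF near 1)", {
  g <- build_lattice_graph(10, 10)
  d <- sim_dataset(g, seed = 27)
  f <- fit_glm(d$Y, d$E, d$Z, mcmc = quick_mcmc(iterations = 6000, burnin = 2000))
  expect_lt(psrf(f), 1.05)
})
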