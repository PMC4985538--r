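# Minimal hand-built draws object for deterministic metric checks.
fake_glm_draws <- function(beta, Y, E, Z, J = 4) {
  beta_mat <- matrix(rep(beta, each = J), J)
  ll <- apply(beta_mat, 1, function(b)
    sum(stats::dpois(Y, E * exp(drop(Z %*% b)), log = TRUE)))
  structure(list(beta = beta_mat, loglik = ll, logprior = rep(0, J),
                 chain = rep(1, J), J = J, model = list(structure = "glm")),
            class = "posterior_draws")
}

test_that("DIC collapses to the plug-in deviance for degenerate draws", {
  g <- build_lattice_graph(4, 4)
  d <- sim_dataset(g, seed = 1)
  bhat <- suppressWarnings(stats::glm.fit(d$Z, d$Y, offset = log(d$E),
                                          family = stats::poisson()))$coefficients
  f <- fake_glm_draws(bhat, d$Y, d$E, d$Z)
  out <- dic(f, d$Y, d$E, d$Z)
  expect_equal(out$p_d, 0, tolerance = 1e-9)
  expect_equal(out$dic, -2 * f$loglik[1], tolerance = 1e-9)
})

test_that("DIC decomposition identity holds and p_d tracks model complexity", {
  g <- build_lattice_graph(10, 10)
  d <- sim_dataset(g, rho = 0.8, tau2 = 0.2, seed = 2)
  mc <- quick_mcmc(iterations = 4000, burnin = 2000)
  fg <- fit_glm(d$Y, d$E, d$Z, mcmc = mc)
  fl <- fit_leroux(d$Y, d$E, d$Z, g, mcmc = mc)
  dg <- dic(fg, d$Y, d$E, d$Z)
  dl <- dic(fl, d$Y, d$E, d$Z)

  # identity DIC = D(eta_bar) + 2 p_D
  eta_bar <- drop(d$Z %*% colMeans(fg$beta))
  dhat <- -2 * sum(stats::dpois(d$Y, d$E * exp(eta_bar), log = TRUE))
  expect_equal(dg$dic, dhat + 2 * dg$p_d, tolerance = 1e-9)

  # GLM has ~3 effective parameters; the CAR model has many more
  expect_equal(dg$p_d, 3, tolerance = 0.7)
  expect_gt(dl$p_d, dg$p_d)
  # and fits the overdispersed data better
  expect_lt(dl$dic, dg$dic)
})

test_that("RMSE matches hand-constructed fitted values", {
  g <- build_lattice_graph(3, 3)
  Y <- c(4, 0, 7, 2, 5, 9, 1, 3, 6)
  E <- rep(1, 9)
  Z <- build_design(seq_len(9), c(2, 1, 4, 3, 6, 5, 8, 7, 9))
  # draws whose fitted values equal Y exactly (log link, E = 1)
  f <- structure(list(beta = matrix(0, 2, 3),
                      phi = matrix(rep(log(pmax(Y, 0.5)), each = 2), 2),
                      loglik = c(0, 0), logprior = c(0, 0), chain = c(1, 2),
                      J = 2, model = list(structure = "leroux")),
                 class = "posterior_draws")
  fitted <- pmax(Y, 0.5)
  expect_equal(rmse(f, Y, E, Z), sqrt(mean((Y - fitted)^2)), tolerance = 1e-10)
  # fitted = Y + 1 everywhere -> RMSE exactly 1
  f$phi <- matrix(rep(log(Y + 1), each = 2), 2)
  expect_equal(rmse(f, Y, E, Z), 1, tolerance = 1e-10)
})

test_that("richer models do not fit worse in RMSE", {
  g <- build_lattice_graph(10, 10)
  d <- sim_dataset(g, rho = 0.8, tau2 = 0.2, seed = 4)
  mc <- quick_mcmc(iterations = 4000, burnin = 2000)
  r_null <- rmse(fit_glm(d$Y, d$E, d$Z, mcmc = mc), d$Y, d$E, d$Z)
  r_sat <- rmse(fit_leroux(d$Y, d$E, d$Z, g, mcmc = mc), d$Y, d$E, d$Z)
  expect_lte(r_sat, r_null)
})

test_that("overdispersion statistic is calibrated and detects inflation", {
  g <- build_lattice_graph(12, 12)
  d <- sim_dataset(g, tau2 = 1e-6, seed = 5)          # equidispersed
  expect_lt(abs(overdispersion_statistic(d$Y, d$E, d$Z) - 1), 0.35)

  # doubled counts: Var(2Y') = 4 mu', mean 2 mu' -> Pearson ratio approx 2
  d2 <- overdispersion_statistic(2 * d$Y, d$E, d$Z)
  expect_equal(d2, 2, tolerance = 0.4)

  Zsmall <- build_design(c(1, 2), c(4, 3))
  expect_error(overdispersion_statistic(c(1, 2), c(1, 1), Zsmall), "more zones")
})
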