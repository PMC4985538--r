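test_that("marginal-likelihood average handles single draws, duplication and the harmonic variant", {
  d1 <- list(loglik = -3.2, logprior = -1.1)
  expect_equal(log_marginal_likelihood(d1), -4.3)

  d <- list(loglik = c(-3, -2.5, -4), logprior = c(-1, -1.2, -0.8))
  v <- log_marginal_likelihood(d)
  dd <- list(loglik = rep(d$loglik, 2), logprior = rep(d$logprior, 2))
  expect_equal(log_marginal_likelihood(dd), v, tolerance = 1e-12)

  expect_equal(log_marginal_likelihood(d, method = "harmonic"),
               -(log(mean(exp(-d$loglik)))), tolerance = 1e-12)
  expect_error(log_marginal_likelihood(list(loglik = numeric(0))), "log-likelihood")
  expect_error(log_marginal_likelihood(list(loglik = c(-1, -2))), "log-prior")
})

test_that("the marginal-likelihood average matches its quadrature estimand on a conjugate toy", {
  # One rate lambda shared by 5 zones: Y_i ~ Poisson(E_i lambda),
  # lambda ~ Gamma(a0, b0).  The Monte-Carlo average of
  # likelihood x prior over posterior draws estimates
  # E_post[f(Y|lambda) f(lambda)], computed here by quadrature.
  Y <- c(3, 7, 2, 5, 4); E <- c(4, 6, 3, 5, 5)
  a0 <- 2; b0 <- 0.5
  ap <- a0 + sum(Y); bp <- b0 + sum(E)
  loglik_fun <- function(l) vapply(l, function(li)
    sum(stats::dpois(Y, E * li, log = TRUE)), numeric(1))
  logprior_fun <- function(l) stats::dgamma(l, a0, b0, log = TRUE)

  integrand <- function(l)
    exp(loglik_fun(l) + logprior_fun(l) + stats::dgamma(l, ap, bp, log = TRUE))
  quad <- stats::integrate(integrand, 0, Inf, rel.tol = 1e-10)$value

  set.seed(99)
  lam <- stats::rgamma(20000, ap, bp)
  est <- exp(log_marginal_likelihood(list(loglik = loglik_fun(lam),
                                          logprior = logprior_fun(lam))))
  expect_equal(est, quad, tolerance = 0.01)
})

test_that("model probabilities are a stable softmax", {
  expect_equal(model_probabilities(5), 1)
  expect_equal(model_probabilities(c(-2, -2)), c(0.5, 0.5))
  expect_equal(model_probabilities(c(0, log(3))), c(0.25, 0.75), tolerance = 1e-12)
  # shift invariance and extreme-value stability
  lm <- c(-12000, -12010, -11995)
  expect_equal(model_probabilities(lm), model_probabilities(lm + 5000),
               tolerance = 1e-12)
  expect_equal(sum(model_probabilities(lm)), 1, tolerance = 1e-12)
  # permutation equivariance
  p <- sample(3)
  expect_equal(model_probabilities(lm[p]), model_probabilities(lm)[p])
  expect_error(model_probabilities(numeric(0)), "no models")
})

test_that("mixture moments match hand calculation and collapse cases", {
  out <- bma_combine(c(0.01, 0.02), c(1e-4, 1e-4), c(0.5, 0.5))
  expect_equal(out$mean, 0.015, tolerance = 1e-15)
  expect_equal(out$var, 1.25e-4, tolerance = 1e-15)
  expect_equal(out$ci95, 0.015 + c(-1, 1) * 1.96 * sqrt(1.25e-4))

  # K = 1 and all-weight-on-one collapse exactly
  one <- bma_combine(0.007, 2e-5, 1)
  expect_equal(one$mean, 0.007)
  expect_equal(one$var, 2e-5)
  onehot <- bma_combine(c(0.007, -0.1), c(2e-5, 4e-3), c(1, 0))
  expect_equal(onehot$mean, 0.007)
  expect_equal(onehot$var, 2e-5)

  # numerical-integration oracle for a two-component normal mixture
  m <- c(0.01, -0.004); v <- c(4e-4, 9e-4); w <- c(0.3, 0.7)
  dens <- function(x) w[1] * stats::dnorm(x, m[1], sqrt(v[1])) +
    w[2] * stats::dnorm(x, m[2], sqrt(v[2]))
  mu <- stats::integrate(function(x) x * dens(x), -1, 1, rel.tol = 1e-12)$value
  second <- stats::integrate(function(x) x^2 * dens(x), -1, 1, rel.tol = 1e-12)$value
  out <- bma_combine(m, v, w)
  expect_equal(out$mean, mu, tolerance = 1e-10)
  expect_equal(out$var, second - mu^2, tolerance = 1e-10)

  expect_error(bma_combine(c(1, 2), c(0.1, -0.1), c(0.5, 0.5)), "non-negative")
  expect_error(bma_combine(c(1, 2), c(0.1, 0.1), c(0.9, 0.5)), "simplex")
})

test_that("combined mean stays within the per-model range", {
  set.seed(7)
  for (k in 1:20) {
    K <- sample(2:6, 1)
    bh <- stats::rnorm(K, 0, 0.01)
    w <- model_probabilities(stats::rnorm(K))
    out <- bma_combine(bh, stats::runif(K, 1e-6, 1e-3), w)
    expect_gte(out$mean, min(bh) - 1e-12)
    expect_lte(out$mean, max(bh) + 1e-12)
  }
})

test_that("tail-probability mixing follows the weights", {
  expect_equal(prob_effect_positive(c(1, 1, 1), c(0.2, 0.3, 0.5)), 1)
  expect_equal(prob_effect_positive(c(0.5, 0.5), c(0.4, 0.6)), 0.5)
  expect_equal(prob_effect_positive(c(0.9, 0.6), c(0.75, 0.25)), 0.825)
})

test_that("end-to-end BMA over fitted models favours the generating structure", {
  g <- build_lattice_graph(10, 10)
  d <- sim_dataset(g, rho = 0.8, tau2 = 0.25, seed = 31)   # strongly spatial
  mc <- quick_mcmc(iterations = 4000, burnin = 2000)
  fits <- list(glm = fit_glm(d$Y, d$E, d$Z, mcmc = mc),
               leroux = fit_leroux(d$Y, d$E, d$Z, g, mcmc = mc))
  res <- bma(fits, labels = names(fits))
  expect_s3_class(res, "bma_result")
  expect_equal(sum(res$weights), 1, tolerance = 1e-12)
  expect_gt(res$weights[2], res$weights[1])
  expect_gte(res$prob_rr_gt1, 0)
  expect_lte(res$prob_rr_gt1, 1)

  stem <- file.path(withr::local_tempdir(), "bma")
  write_bma_report(res, stem)
  j <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  expect_equal(j$combined_rr, res$combined$rr, tolerance = 1e-12)
})
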