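# Shared fixtures: small graphs and simulated datasets, built in code.

path_graph <- function(n) {
  W <- matrix(0, n, n)
  for (i in seq_len(n - 1)) W[i, i + 1] <- W[i + 1, i] <- 1
  area_graph(W, centroids = cbind(seq_len(n), rep(0, n)))
}

# random connected graph: random spanning tree plus extra random edges
random_graph <- function(n, extra = n, seed = 1) {
  set.seed(seed)
  W <- matrix(0, n, n)
  for (i in 2:n) {
    j <- sample.int(i - 1, 1)
    W[i, j] <- W[j, i] <- 1
  }
  for (k in seq_len(extra)) {
    ij <- sample.int(n, 2)
    W[ij[1], ij[2]] <- W[ij[2], ij[1]] <- 1
  }
  diag(W) <- 0
  area_graph(W)
}

quick_mcmc <- function(chains = 3, iterations = 3000, burnin = 1000,
                       thin = 2, seed = 1) {
  mcmc_config(chains = chains, iterations = iterations, burnin = burnin,
              thin = thin, seed = seed)
}

# Poisson dataset simulated from the spatial model on a lattice; iid
# covariates so the exposure effect is well identified.
sim_dataset <- function(g, rr = 1.05, rho = 0.7, tau2 = 0.1, seed = 1,
                        beta3 = 0.05) {
  set.seed(seed)
  x <- stats::rnorm(g$n, 18, 6)
  u <- stats::rnorm(g$n)
  Z <- build_design(x, u)
  E <- generate_population(g, seed = seed + 1)$E
  b2 <- beta_for_rr(rr)
  b1 <- log(1.066) - log(mean(exp(b2 * x + beta3 * u))) - tau2 / 2
  truth <- scenario_truth(c(b1, b2, beta3), rho = rho, tau2 = tau2,
                          seed = seed + 2)
  gen <- generate_counts(E, Z, truth, g)
  list(Y = gen$counts$Y, E = E, Z = Z, truth = gen$truth, graph = g)
}
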