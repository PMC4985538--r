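#' Prior specification for the Poisson log-linear models
#'
#' Weakly informative defaults common in disease mapping: regression
#' coefficients \code{beta ~ N(m, V)} with \code{m = 0} and a large
#' diagonal \code{V}; variance scale \code{tau2 ~ inverse-gamma(a, b)};
#' dependence \code{rho ~ uniform(0, 1)} (Leroux model only).
#'
#' @param m prior mean vector for beta (recycled to length p at fit time).
#' @param v prior variance for each coefficient (diagonal of V).
#' @param a,b inverse-gamma shape and scale for tau2.
#' @return object of class \code{prior_spec}.
#' @export
prior_spec <- function(m = 0, v = 1e5, a = 1, b = 0.01) {
  if (any(v <= 0)) stop("prior variances must be positive")
  if (a <= 0 || b <= 0) stop("inverse-gamma parameters must be positive")
  structure(list(m = m, v = v, a = a, b = b), class = "prior_spec")
}

#' MCMC configuration
#'
#' Defaults follow the protocol used for every model in the package's
#' reference analysis: 5 parallel chains of 120,000 iterations each, the
#' first 20,000 discarded as burn-in and the remainder thinned by 10,
#' retaining 50,000 draws in total.  \code{(iterations - burnin)} must be
#' divisible by \code{thin}.  Proposal scales adapt toward roughly 40%
#' acceptance during burn-in only.
#'
#' @param chains number of chains.
#' @param iterations iterations per chain.
#' @param burnin burn-in iterations per chain (< iterations).
#' @param thin thinning interval (>= 1).
#' @param seed integer master seed; chain c uses \code{seed + c - 1}.
#' @return object of class \code{mcmc_config}.
#' @export
mcmc_config <- function(chains = 5, iterations = 120000, burnin = 20000,
                        thin = 10, seed = 1) {
  if (burnin >= iterations) stop("burnin must be smaller than iterations")
  if (thin < 1) stop("thin must be >= 1")
  if ((iterations - burnin) %% thin != 0)
    stop("(iterations - burnin) must be divisible by thin")
  if (chains < 1) stop("need at least one chain")
  structure(list(chains = chains, iterations = iterations, burnin = burnin,
                 thin = thin, seed = as.integer(seed)),
            class = "mcmc_config")
}

#' Retained draws per configuration
#' @param mcmc an \code{mcmc_config}.
#' @return total retained draw count across chains.
#' @export
retained_draws <- function(mcmc) {
  mcmc$chains * (mcmc$iterations - mcmc$burnin) %/% mcmc$thin
}

#' Build the regression design matrix
#'
#' Fixed column order \code{[1, exposure, deprivation]} so that the second
#' coefficient is always the exposure effect.  Constant columns are
#' rejected (collinear with the intercept).
#'
#' @param exposure,deprivation numeric vectors of equal length.
#' @return n x 3 matrix with columns \code{intercept, exposure, deprivation}.
#' @export
build_design <- function(exposure, deprivation) {
  if (length(exposure) != length(deprivation)) stop("covariate lengths differ")
  if (!all(is.finite(exposure)) || !all(is.finite(deprivation)))
    stop("covariates must be finite")
  if (stats::var(exposure) == 0) stop("exposure is constant (collinear with intercept)")
  if (stats::var(deprivation) == 0) stop("deprivation is constant (collinear with intercept)")
  cbind(intercept = 1, exposure = exposure, deprivation = deprivation)
}

check_fit_inputs <- function(Y, E, Z) {
  n <- length(Y)
  if (length(E) != n || nrow(Z) != n) stop("Y, E and Z dimensions disagree")
  if (any(E <= 0)) stop("expected counts E must be positive")
  if (any(Y < 0) || any(Y != round(Y))) stop("Y must be non-negative integers")
  if (qr(Z)$rank < ncol(Z)) stop("design matrix is rank deficient")
  invisible(n)
}

# Deterministic ML fit used for initial values and proposal scales.
glm_start <- function(Y, E, Z) {
  fit <- suppressWarnings(
    stats::glm.fit(Z, Y, offset = log(E), family = stats::poisson()))
  beta <- fit$coefficients
  w <- fit$weights
  XtWX <- crossprod(Z * sqrt(w))
  se <- sqrt(diag(solve(XtWX)))
  list(beta = beta, se = se)
}

expand_priors <- function(priors, p) {
  list(m = rep_len(priors$m, p), v = rep_len(priors$v, p),
       a = priors$a, b = priors$b)
}

new_posterior_draws <- function(chains_out, fields, mcmc, priors, model) {
  res <- list()
  scalar_fields <- c("loglik", "logprior", "rho", "tau2")
  for (f in fields) {
    parts <- lapply(chains_out, `[[`, f)
    res[[f]] <- do.call(rbind, lapply(parts, as.matrix))
    if (f %in% scalar_fields) res[[f]] <- drop(res[[f]])
  }
  per <- nrow(chains_out[[1]]$beta)
  res$chain <- rep(seq_along(chains_out), each = per)
  res$J <- per * length(chains_out)
  res$accept <- lapply(grep("^accept", names(chains_out[[1]]), value = TRUE), function(nm)
    mean(vapply(chains_out, `[[`, numeric(1), nm)))
  names(res$accept) <- grep("^accept", names(chains_out[[1]]), value = TRUE)
  res$mcmc <- mcmc
  res$priors <- priors
  res$model <- model
  class(res) <- "posterior_draws"
  res
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat("posterior_draws:", x$model$structure, "model,", x$J, "retained draws (",
      x$mcmc$chains, "chains )\n")
  s <- summarise_fit(x)
  cat(sprintf("  RR per 5 units: %.3f (%.3f, %.3f)\n", s$rr, s$rr_lower, s$rr_upper))
  invisible(x)
}

#' Fit the non-spatial Poisson GLM (Model 1)
#'
#' Bayesian Poisson log-linear model \code{Y_i ~ Poisson(E_i R_i)},
#' \code{log R_i = z_i' beta}, with no random effects: residual spatial
#' autocorrelation and overdispersion are ignored.  beta is sampled by
#' adaptive joint random-walk Metropolis; per-draw log-likelihood and
#' log-prior are retained for model averaging.
#'
#' @param Y observed counts (length n).
#' @param E expected counts (positive, length n).
#' @param Z design matrix from \code{\link{build_design}}.
#' @param priors a \code{\link{prior_spec}}.
#' @param mcmc an \code{\link{mcmc_config}}.
#' @return object of class \code{posterior_draws} with elements
#'   \code{beta} (J x p), \code{loglik}, \code{logprior}, \code{chain},
#'   acceptance rates and config echoes.
#' @export
fit_glm <- function(Y, E, Z, priors = prior_spec(), mcmc = mcmc_config()) {
  check_fit_inputs(Y, E, Z)
  p <- ncol(Z)
  pr <- expand_priors(priors, p)
  st <- glm_start(Y, E, Z)
  chains_out <- lapply(seq_len(mcmc$chains), function(ch) {
    set.seed(mcmc$seed + ch - 1)
    glm_chain(Y, E, Z, pr$m, pr$v, st$beta, st$se,
              mcmc$iterations, mcmc$burnin, mcmc$thin)
  })
  new_posterior_draws(chains_out, c("beta", "loglik", "logprior"),
                      mcmc, priors, list(structure = "glm"))
}

# Adjacency in flat 0-based form for the C++ kernel, plus the eigenvalues
# of diag(W1) - W (so log det [rho(D-W) + (1-rho)I] is a cheap sum).
graph_for_sampler <- function(graph) {
  adj <- lapply(seq_len(graph$n), function(i) which(graph$W[i, ] == 1) - 1L)
  list(adj = as.integer(unlist(adj)),
       adj_start = as.integer(c(0, cumsum(lengths(adj)))),
       degree = graph$degree,
       edge_i = as.integer(graph$edges[, "i"] - 1L),
       edge_j = as.integer(graph$edges[, "j"] - 1L),
       lambda = eigen(diag(graph$degree) - graph$W, symmetric = TRUE,
                      only.values = TRUE)$values)
}

#' Fit the Leroux CAR model (Model 2)
#'
#' Adds zone-level random effects \code{phi} under the Leroux conditional
#' autoregressive prior: each full conditional is normal with mean
#' \code{rho * sum_j w_ij phi_j / (rho * d_i + 1 - rho)} and variance
#' \code{tau2 / (rho * d_i + 1 - rho)}.  Sampling: joint random-walk MH
#' for beta, single-site MH for each phi_i, conjugate inverse-gamma for
#' tau2 (shape \code{a + n/2}), and logit-scale MH for rho under its
#' uniform(0,1) prior.  phi is mean-centred every iteration so the
#' intercept is identified.  The per-draw log-prior includes all of beta,
#' phi, tau2 and rho.
#'
#' @inheritParams fit_glm
#' @param graph an \code{\link{area_graph}} (connected; islands rejected).
#' @return \code{posterior_draws} with additional elements \code{phi}
#'   (J x n), \code{rho}, \code{tau2}.
#' @export
fit_leroux <- function(Y, E, Z, graph, priors = prior_spec(), mcmc = mcmc_config()) {
  stopifnot(inherits(graph, "area_graph"))
  n <- check_fit_inputs(Y, E, Z)
  if (graph$n != n) stop("graph size does not match data")
  p <- ncol(Z)
  pr <- expand_priors(priors, p)
  st <- glm_start(Y, E, Z)
  gs <- graph_for_sampler(graph)
  chains_out <- lapply(seq_len(mcmc$chains), function(ch) {
    set.seed(mcmc$seed + ch - 1)
    leroux_chain(Y, E, Z, pr$m, pr$v, pr$a, pr$b,
                 gs$adj, gs$adj_start, gs$degree, gs$edge_i, gs$edge_j,
                 gs$lambda, st$beta, st$se, 0.5, 0.01,
                 mcmc$iterations, mcmc$burnin, mcmc$thin)
  })
  new_posterior_draws(chains_out,
                      c("beta", "phi", "rho", "tau2", "loglik", "logprior"),
                      mcmc, priors, list(structure = "leroux"))
}

#' Orthogonal spatial basis
#'
#' Builds the eigenvector basis for orthogonal smoothing (restricted
#' spatial regression).  With hat matrix \code{P = Z (Z'Z)^-1 Z'} and
#' residual projector \code{P' = I - P}, the eigenvectors of
#' \code{P' W P'} span all spatial patterns orthogonal to the covariates;
#' positive eigenvalues correspond to positively autocorrelated patterns.
#' The first \code{q} eigenvectors with the largest positive eigenvalues
#' form \code{M}; the smoothing prior precision is
#' \code{Qs = M' (diag(W1) - W) M}, the intrinsic-CAR precision projected
#' onto the basis.
#'
#' @param Z full-column-rank design matrix.
#' @param graph an \code{\link{area_graph}}.
#' @param q number of eigenvectors to retain (default 50); must not exceed
#'   the number of strictly positive eigenvalues of \code{P' W P'}.
#' @return object of class \code{orthogonal_basis}: list with \code{M}
#'   (n x q), \code{eigenvalues} (descending, positive), \code{Qs},
#'   \code{logdetQs}.
#' @export
build_orthogonal_basis <- function(Z, graph, q = 50) {
  stopifnot(inherits(graph, "area_graph"))
  if (qr(Z)$rank < ncol(Z)) stop("design matrix is rank deficient")
  n <- graph$n
  if (nrow(Z) != n) stop("Z and graph sizes disagree")
  P <- Z %*% solve(crossprod(Z), t(Z))
  Pr <- diag(n) - P
  ev <- eigen(Pr %*% graph$W %*% Pr, symmetric = TRUE)
  pos <- which(ev$values > 1e-10)
  if (q > length(pos))
    stop("q = ", q, " exceeds the number of strictly positive eigenvalues (",
         length(pos), ")")
  keep <- pos[seq_len(q)]          # eigen() sorts descending
  M <- ev$vectors[, keep, drop = FALSE]
  R <- diag(graph$degree) - graph$W
  Qs <- crossprod(M, R %*% M)
  Qs <- (Qs + t(Qs)) / 2
  ld <- determinant(Qs, logarithm = TRUE)
  if (ld$sign <= 0) stop("projected precision Qs is not positive definite")
  structure(list(M = M, eigenvalues = ev$values[keep], Qs = Qs,
                 logdetQs = as.numeric(ld$modulus)),
            class = "orthogonal_basis")
}

#' Fit the orthogonal smoothing model (Model 3)
#'
#' Replaces the full CAR field by a low-dimensional field
#' \code{log R_i = z_i' beta + m_i' delta}, where the columns of \code{M}
#' are the leading positive eigenvectors of \code{P' W P'}
#' (\code{\link{build_orthogonal_basis}}) and
#' \code{delta ~ N(0, tau2 * Qs^-1)}.  Because every basis column is
#' orthogonal to the covariates, spatial confounding between the smooth
#' term and the exposure effect is removed by construction.  Sampling:
#' joint MH for beta, single-site MH for delta, conjugate inverse-gamma
#' for tau2 (shape \code{a + q/2}).
#'
#' @inheritParams fit_leroux
#' @param q eigenvector count (default 50).
#' @return \code{posterior_draws} with elements \code{delta} (J x q) and
#'   \code{tau2}; the basis is stored in \code{$model$basis}.
#' @export
fit_orthogonal <- function(Y, E, Z, graph, priors = prior_spec(),
                           mcmc = mcmc_config(), q = 50) {
  stopifnot(inherits(graph, "area_graph"))
  n <- check_fit_inputs(Y, E, Z)
  if (graph$n != n) stop("graph size does not match data")
  p <- ncol(Z)
  pr <- expand_priors(priors, p)
  st <- glm_start(Y, E, Z)
  basis <- build_orthogonal_basis(Z, graph, q)
  chains_out <- lapply(seq_len(mcmc$chains), function(ch) {
    set.seed(mcmc$seed + ch - 1)
    orthogonal_chain(Y, E, Z, pr$m, pr$v, pr$a, pr$b,
                     basis$M, basis$Qs, basis$logdetQs, st$beta, st$se,
                     0.01, mcmc$iterations, mcmc$burnin, mcmc$thin)
  })
  new_posterior_draws(chains_out,
                      c("beta", "delta", "tau2", "loglik", "logprior"),
                      mcmc, priors,
                      list(structure = "orthogonal", q = q, basis = basis))
}

#' Posterior summary of a fitted model
#'
#' Posterior median and variance of the exposure coefficient, the relative
#' risk per increment with a quantile-based 95% credible interval, and the
#' draw-based probability that the exposure effect is positive.
#'
#' @param draws a \code{posterior_draws} object.
#' @param increment exposure increment for the RR scale (default 5).
#' @return list with \code{beta2_median}, \code{beta2_var}, \code{rr},
#'   \code{rr_lower}, \code{rr_upper}, \code{p_positive}.
#' @export
summarise_fit <- function(draws, increment = 5) {
  b2 <- draws$beta[, 2]
  qs <- stats::quantile(b2, c(0.025, 0.5, 0.975), names = FALSE)
  list(beta2_median = qs[2],
       beta2_var = stats::var(b2),
       rr = rr_per_increment(qs[2], increment),
       rr_lower = rr_per_increment(qs[1], increment),
       rr_upper = rr_per_increment(qs[3], increment),
       p_positive = mean(b2 > 0))
}

#' Potential scale reduction factor
#'
#' Gelman-Rubin convergence diagnostic for a scalar parameter across the
#' chains of a fit (default: the exposure coefficient).
#'
#' @param draws a \code{posterior_draws} object, or a numeric matrix with
#'   one column per chain.
#' @param param column of \code{draws$beta} to monitor (default 2).
#' @return the PSRF (values near 1 indicate convergence).
#' @export
psrf <- function(draws, param = 2) {
  if (inherits(draws, "posterior_draws")) {
    x <- draws$beta[, param]
    mat <- do.call(cbind, split(x, draws$chain))
  } else mat <- as.matrix(draws)
  m <- ncol(mat); n <- nrow(mat)
  if (m < 2) stop("PSRF needs at least two chains")
  means <- colMeans(mat)
  B <- n * stats::var(means)
  W <- mean(apply(mat, 2, stats::var))
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Recompute the per-draw log-likelihood from stored parameters
#'
#' Bookkeeping check: rebuilds the linear predictor of every retained draw
#' from the stored \code{beta} (and \code{phi} or \code{delta}) and
#' re-evaluates the Poisson log-likelihood; the result should match the
#' stored \code{loglik} to numerical round-off.
#'
#' @param draws a \code{posterior_draws} object.
#' @param Y,E,Z the data the model was fitted to.
#' @return numeric vector of length J.
#' @export
recompute_loglik <- function(draws, Y, E, Z) {
  eta <- draws$beta %*% t(Z)
  if (!is.null(draws$phi)) eta <- eta + draws$phi
  if (!is.null(draws$delta)) eta <- eta + draws$delta %*% t(draws$model$basis$M)
  const <- sum(lgamma(Y + 1))
  apply(eta, 1, function(h) sum(Y * (log(E) + h) - E * exp(h)) - const)
}

#' Persist and reload posterior draws
#'
#' One CSV row per retained draw (chain, parameters, loglik, logprior)
#' plus a JSON sidecar echoing the model structure, priors and MCMC
#' configuration.
#'
#' @param draws a \code{posterior_draws} object.
#' @param stem file stem; writes \code{<stem>.csv} and \code{<stem>.json}.
#' @return \code{read_draws} returns a \code{posterior_draws} object
#'   (without the orthogonal basis matrix, which is reconstructable from
#'   the data and graph).
#' @export
write_draws <- function(draws, stem) {
  df <- data.frame(chain = draws$chain)
  for (k in seq_len(ncol(draws$beta))) df[[paste0("beta", k)]] <- draws$beta[, k]
  if (!is.null(draws$phi))
    for (k in seq_len(ncol(draws$phi))) df[[paste0("phi", k)]] <- draws$phi[, k]
  if (!is.null(draws$delta))
    for (k in seq_len(ncol(draws$delta))) df[[paste0("delta", k)]] <- draws$delta[, k]
  if (!is.null(draws$rho)) df$rho <- draws$rho
  if (!is.null(draws$tau2)) df$tau2 <- draws$tau2
  df$loglik <- draws$loglik
  df$logprior <- draws$logprior
  utils::write.csv(df, paste0(stem, ".csv"), row.names = FALSE)
  side <- list(structure = draws$model$structure,
               q = draws$model$q,
               mcmc = unclass(draws$mcmc),
               priors = unclass(draws$priors),
               accept = draws$accept)
  jsonlite::write_json(side, paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' @rdname write_draws
#' @export
read_draws <- function(stem) {
  df <- utils::read.csv(paste0(stem, ".csv"))
  side <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  grab <- function(prefix) {
    cols <- grep(paste0("^", prefix, "[0-9]+$"), names(df), value = TRUE)
    if (length(cols) == 0) return(NULL)
    as.matrix(df[, cols[order(as.integer(sub(prefix, "", cols)))], drop = FALSE])
  }
  res <- list(beta = grab("beta"), phi = grab("phi"), delta = grab("delta"),
              rho = df$rho, tau2 = df$tau2,
              loglik = df$loglik, logprior = df$logprior,
              chain = df$chain, J = nrow(df),
              mcmc = side$mcmc, priors = side$priors,
              model = list(structure = side$structure, q = side$q),
              accept = side$accept)
  res[vapply(res, is.null, logical(1))] <- NULL
  class(res) <- "posterior_draws"
  res
}
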