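# Per-draw linear predictors, chunked over draws to bound memory.
# f receives an (chunk x n) matrix of eta values and the row indices.
eta_apply <- function(draws, Z, f, chunk = 2000) {
  J <- draws$J
  M <- if (!is.null(draws$delta)) draws$model$basis$M else NULL
  for (start in seq(1, J, by = chunk)) {
    idx <- start:min(start + chunk - 1, J)
    eta <- draws$beta[idx, , drop = FALSE] %*% t(Z)
    if (!is.null(draws$phi)) eta <- eta + draws$phi[idx, , drop = FALSE]
    if (!is.null(M)) eta <- eta + draws$delta[idx, , drop = FALSE] %*% t(M)
    f(eta, idx)
  }
  invisible(NULL)
}

posterior_mean_eta <- function(draws, Z) {
  eta <- drop(Z %*% colMeans(draws$beta))
  if (!is.null(draws$phi)) eta <- eta + colMeans(draws$phi)
  if (!is.null(draws$delta))
    eta <- eta + drop(draws$model$basis$M %*% colMeans(draws$delta))
  eta
}

#' Deviance information criterion
#'
#' DIC for a fitted Poisson model, from the retained draws' stored
#' log-likelihoods: with deviance \code{D(theta) = -2 log f(Y | theta)},
#' the effective number of parameters is
#' \code{p_D = mean(D) - D(theta_bar)} and \code{DIC = mean(D) + p_D}.
#' "Posterior mean parameters" are summarised through the posterior mean
#' of the linear predictor, which is well defined for all three model
#' structures (and, the predictor being linear in the parameters, equal to
#' plugging in the posterior mean of each parameter block).  Deviances
#' include the full Poisson normalising constants, applied consistently,
#' so differences between models are meaningful.
#'
#' @param draws a \code{posterior_draws} object carrying \code{loglik}.
#' @param Y,E,Z the data the model was fitted to.
#' @return list with \code{dic} and \code{p_d}.
#' @export
dic <- function(draws, Y, E, Z) {
  if (is.null(draws$loglik)) stop("draws carry no log-likelihood")
  dbar <- mean(-2 * draws$loglik)
  eta_bar <- posterior_mean_eta(draws, Z)
  dhat <- -2 * sum(stats::dpois(Y, E * exp(eta_bar), log = TRUE))
  p_d <- dbar - dhat
  list(dic = dbar + p_d, p_d = p_d)
}

#' Root mean square error of the fitted values
#'
#' \code{sqrt(mean((Y_i - fitted_i)^2))} where the fitted value for zone i
#' is the posterior mean of \code{E_i R_i}, averaged over retained draws.
#'
#' @inheritParams dic
#' @return a single number on the count scale.
#' @export
rmse <- function(draws, Y, E, Z) {
  n <- length(Y)
  acc <- numeric(n)
  eta_apply(draws, Z, function(eta, idx) acc <<- acc + colSums(exp(eta)))
  fitted <- E * acc / draws$J
  sqrt(mean((Y - fitted)^2))
}

#' Overdispersion statistic of a Poisson GLM
#'
#' Pearson chi-squared divided by residual degrees of freedom,
#' \code{X^2 / (n - p)}, from a deterministic maximum-likelihood Poisson
#' fit of \code{Y ~ Z + offset(log E)}.  Values near 1 indicate
#' equidispersion; substantially larger values indicate overdispersion,
#' typically from unmodelled spatial structure.
#'
#' @param Y,E,Z areal counts, expected counts and design matrix.
#' @return the overdispersion estimate.
#' @export
overdispersion_statistic <- function(Y, E, Z) {
  n <- length(Y); p <- ncol(Z)
  if (n <= p) stop("need more zones than regression parameters")
  if (qr(Z)$rank < p) stop("design matrix is rank deficient")
  fit <- suppressWarnings(
    stats::glm.fit(Z, Y, offset = log(E), family = stats::poisson()))
  mu <- fit$fitted.values
  sum((Y - mu)^2 / mu) / (n - p)
}

#' Pearson residuals of a Poisson GLM
#'
#' Deterministic ML fit residuals \code{(Y - mu) / sqrt(mu)}, the input to
#' the Moran's I autocorrelation test.
#'
#' @inheritParams overdispersion_statistic
#' @return numeric vector of length n.
#' @export
glm_pearson_residuals <- function(Y, E, Z) {
  fit <- suppressWarnings(
    stats::glm.fit(Z, Y, offset = log(E), family = stats::poisson()))
  (Y - fit$fitted.values) / sqrt(fit$fitted.values)
}
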