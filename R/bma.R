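logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Monte-Carlo marginal-likelihood approximation
#'
#' Approximates the marginal likelihood of a model by averaging
#' likelihood times prior over the retained posterior draws:
#' \deqn{f(Y | M_k) \approx \frac{1}{J} \sum_{j=1}^{J}
#'   f(Y | \theta_k^{(j)}) f(\theta_k^{(j)} | M_k),}
#' computed stably on the log scale.  Note that, evaluated with
#' \emph{posterior} samples, this average converges to the posterior
#' expectation of likelihood-times-prior rather than to the
#' prior-predictive integral; it is implemented exactly in this form
#' because it is the estimator the model-averaging procedure is defined
#' with, and a clearly labelled harmonic-mean alternative
#' (\code{method = "harmonic"}) is provided for comparison.
#'
#' @param draws any object carrying numeric \code{loglik} and
#'   \code{logprior} vectors of equal length (one entry per retained
#'   draw), e.g. a \code{posterior_draws} fit.
#' @param method \code{"average"} (the estimator above, default) or
#'   \code{"harmonic"} (harmonic mean of the likelihoods).
#' @return log of the approximated marginal likelihood.
#' @export
log_marginal_likelihood <- function(draws, method = c("average", "harmonic")) {
  method <- match.arg(method)
  ll <- draws$loglik
  if (is.null(ll) || !length(ll)) stop("draws carry no log-likelihood")
  if (method == "average") {
    lp <- draws$logprior
    if (is.null(lp)) stop("draws carry no log-prior")
    if (length(lp) != length(ll)) stop("loglik and logprior lengths differ")
    terms <- ll + lp
    if (all(terms == -Inf)) stop("all likelihood-times-prior terms are zero")
    logsumexp(terms) - log(length(terms))
  } else {
    -(logsumexp(-ll) - log(length(ll)))
  }
}

#' Posterior model probabilities
#'
#' Under a discrete uniform prior over the K candidate models, the
#' posterior probability of model k is its marginal likelihood divided by
#' the sum over models: a softmax of the log marginal likelihoods,
#' computed after subtracting the maximum so that the weights are stable.
#' Underflow of a very poor model to exactly zero weight is permitted.
#'
#' @param log_margliks numeric vector of log marginal likelihoods.
#' @return simplex weight vector (non-negative, sums to 1).
#' @export
model_probabilities <- function(log_margliks) {
  if (length(log_margliks) == 0) stop("no models supplied")
  if (any(is.na(log_margliks))) stop("log marginal likelihoods must be non-missing")
  w <- exp(log_margliks - max(log_margliks))
  w / sum(w)
}

#' Combine per-model estimates into a model-averaged effect
#'
#' Mixture moments of the exposure coefficient across models:
#' \deqn{E(\beta_2 | Y) = \sum_k \hat\beta_{2k} w_k, \quad
#'       Var(\beta_2 | Y) = \sum_k [Var(\beta_2 | M_k, Y) +
#'       \hat\beta_{2k}^2] w_k - E(\beta_2 | Y)^2,}
#' with \eqn{\hat\beta_{2k}} the posterior median under model k and
#' \eqn{w_k} its posterior model probability.  The 95% interval uses a
#' normal approximation, \code{E +/- 1.96 sqrt(Var)}, on the coefficient
#' scale, then exponentiates to the relative-risk scale.
#'
#' @param beta_hat per-model posterior medians of the exposure coefficient.
#' @param beta_var per-model posterior variances (non-negative).
#' @param weights simplex weights from \code{\link{model_probabilities}}.
#' @param increment exposure increment for the RR scale (default 5).
#' @return list with \code{mean}, \code{var}, \code{ci95} (coefficient
#'   scale), and \code{rr}, \code{rr_ci95} (relative-risk scale).
#' @export
bma_combine <- function(beta_hat, beta_var, weights, increment = 5) {
  K <- length(beta_hat)
  if (length(beta_var) != K || length(weights) != K) stop("input lengths differ")
  if (any(beta_var < 0)) stop("within-model variances must be non-negative")
  if (abs(sum(weights) - 1) > 1e-8 || any(weights < 0))
    stop("weights must lie on the simplex")
  m <- sum(beta_hat * weights)
  v <- sum((beta_var + beta_hat^2) * weights) - m^2
  v <- max(v, 0)  # guard round-off on the mixture identity
  ci <- m + c(-1, 1) * 1.96 * sqrt(v)
  list(mean = m, var = v, ci95 = ci,
       rr = rr_per_increment(m, increment),
       rr_ci95 = rr_per_increment(ci, increment))
}

#' Model-averaged probability of a positive exposure effect
#'
#' Mixes per-model tail probabilities: \code{sum_k w_k P(beta2 > 0 | M_k,
#' Y)}, each per-model probability being the fraction of retained draws
#' with a positive exposure coefficient.  (The alternative tail
#' probability implied by the combined normal approximation is available
#' from \code{\link{bma_combine}} output as
#' \code{pnorm(0, mean, sqrt(var), lower.tail = FALSE)}.)
#'
#' @param p_positive per-model probabilities of a positive effect.
#' @param weights simplex weights.
#' @return probability in [0, 1].
#' @export
prob_effect_positive <- function(p_positive, weights) {
  if (length(p_positive) == 0) stop("no models supplied")
  if (length(p_positive) != length(weights)) stop("input lengths differ")
  sum(weights * p_positive)
}

#' Bayesian model averaging over a list of fitted models
#'
#' Full BMA pipeline: per-model log marginal likelihoods (Monte-Carlo
#' average of likelihood times prior), posterior model probabilities
#' under a uniform model prior, mixture moments of the exposure
#' coefficient, and the model-averaged probability that the relative risk
#' exceeds 1.
#'
#' @param fits list of \code{posterior_draws} objects (or per-model
#'   summary lists carrying \code{logml}, \code{beta2_median},
#'   \code{beta2_var}, \code{p_positive}).
#' @param increment exposure increment for the RR scale.
#' @param labels optional model labels.
#' @return object of class \code{bma_result}: list with \code{K},
#'   \code{weights}, \code{log_marglik}, \code{combined} (from
#'   \code{\link{bma_combine}}), \code{prob_rr_gt1}, \code{per_model}.
#' @export
bma <- function(fits, increment = 5, labels = NULL) {
  if (length(fits) == 0) stop("no models supplied")
  per <- lapply(fits, function(f) {
    if (inherits(f, "posterior_draws")) {
      s <- summarise_fit(f, increment)
      list(logml = log_marginal_likelihood(f),
           beta2_median = s$beta2_median, beta2_var = s$beta2_var,
           p_positive = s$p_positive, rr = s$rr,
           rr_lower = s$rr_lower, rr_upper = s$rr_upper)
    } else f
  })
  logml <- vapply(per, `[[`, numeric(1), "logml")
  w <- model_probabilities(logml)
  comb <- bma_combine(vapply(per, `[[`, numeric(1), "beta2_median"),
                      vapply(per, `[[`, numeric(1), "beta2_var"),
                      w, increment)
  structure(list(K = length(per), weights = w, log_marglik = logml,
                 combined = comb,
                 prob_rr_gt1 = prob_effect_positive(
                   vapply(per, `[[`, numeric(1), "p_positive"), w),
                 per_model = per,
                 labels = labels %||% paste0("model_", seq_along(per))),
            class = "bma_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.bma_result <- function(x, ...) {
  cat("Bayesian model averaging over", x$K, "models\n")
  cat(sprintf("  combined RR per increment: %.3f (%.3f, %.3f)\n",
              x$combined$rr, x$combined$rr_ci95[1], x$combined$rr_ci95[2]))
  cat(sprintf("  P(RR > 1) = %.3f\n", x$prob_rr_gt1))
  ord <- order(x$weights, decreasing = TRUE)
  top <- utils::head(ord, 5)
  cat("  top model weights:\n")
  for (k in top)
    cat(sprintf("    %-28s %6.2f%%\n", x$labels[k], 100 * x$weights[k]))
  invisible(x)
}

#' Write a BMA report
#'
#' JSON plus a human-readable per-model table (weights sorted descending,
#' combined RR, interval, P(RR > 1)).
#'
#' @param result a \code{bma_result}.
#' @param stem file stem; writes \code{<stem>.json} and \code{<stem>.csv}.
#' @export
write_bma_report <- function(result, stem) {
  ord <- order(result$weights, decreasing = TRUE)
  tab <- data.frame(model = result$labels[ord],
                    weight = result$weights[ord],
                    log_marglik = result$log_marglik[ord],
                    rr = vapply(result$per_model[ord], function(p)
                      p$rr %||% NA_real_, numeric(1)))
  utils::write.csv(tab, paste0(stem, ".csv"), row.names = FALSE)
  jsonlite::write_json(
    list(K = result$K,
         combined_rr = result$combined$rr,
         rr_ci95 = result$combined$rr_ci95,
         beta_mean = result$combined$mean,
         beta_var = result$combined$var,
         prob_rr_gt1 = result$prob_rr_gt1,
         weights = stats::setNames(as.list(result$weights), result$labels)),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}
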