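#' CAR precision matrices
#'
#' Constructs the joint precision matrix of a conditional autoregressive
#' Gaussian field over an areal graph.  The Leroux family interpolates,
#' through a dependence parameter \code{rho} in [0, 1], between independence
#' (\code{rho = 0}, precision the identity) and the intrinsic CAR
#' (\code{rho = 1}, precision \code{diag(W1) - W}, which is singular with
#' rank \code{n - c} for \code{c} connected components):
#'
#' \deqn{Q = (1/\tau^2) [\rho (diag(W 1) - W) + (1 - \rho) I].}
#'
#' The univariate full conditionals implied by this joint distribution are
#' normal with mean \eqn{\rho \sum_j w_{ij} \phi_j / (\rho \sum_j w_{ij} +
#' 1 - \rho)} and variance \eqn{\tau^2 / (\rho \sum_j w_{ij} + 1 - \rho)},
#' the form in which the prior is usually written in disease mapping.
#'
#' @param graph an \code{\link{area_graph}}.
#' @param rho spatial dependence parameter in [0, 1].
#' @param tau2 conditional variance scale, > 0.
#' @return An object of class \code{precision_matrix}: list with \code{Q}
#'   (n x n), \code{rho}, \code{tau2} and \code{kind} (\code{"leroux"}, or
#'   \code{"intrinsic"} when \code{rho = 1}).
#' @export
leroux_precision <- function(graph, rho, tau2) {
  stopifnot(inherits(graph, "area_graph"))
  if (!is.finite(rho) || rho < 0 || rho > 1) stop("rho must lie in [0, 1]")
  if (!is.finite(tau2) || tau2 <= 0) stop("tau2 must be positive")
  R <- diag(graph$degree) - graph$W
  Q <- (rho * R + (1 - rho) * diag(graph$n)) / tau2
  structure(list(Q = Q, rho = rho, tau2 = tau2,
                 kind = if (rho == 1) "intrinsic" else "leroux"),
            class = "precision_matrix")
}

#' Full-conditional moments of a CAR component
#'
#' Given a joint precision matrix, returns the conditional mean factor and
#' variance of component \code{i} given all others by direct Gaussian
#' conditioning: mean \eqn{-(1/Q_{ii}) \sum_{j \ne i} Q_{ij} \phi_j},
#' variance \eqn{1 / Q_{ii}}.  Used to verify that the Leroux joint
#' distribution reproduces the textbook CAR full conditionals.
#'
#' @param prec a \code{precision_matrix}.
#' @param phi current field values (length n).
#' @param i component index.
#' @return list with \code{mean} and \code{var}.
#' @export
car_full_conditional <- function(prec, phi, i) {
  Q <- prec$Q
  list(mean = -sum(Q[i, -i] * phi[-i]) / Q[i, i],
       var  = 1 / Q[i, i])
}
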