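#' Default deprivation correlation structure
#'
#' Target correlation matrix for the six deprivation domains (access to
#' services, crime, education/skills/training, employment, income,
#' housing).  The default values reproduce the strong
#' income-employment-education block, moderate crime and housing
#' correlations, and the negative correlations of the access domain that
#' characterise Scottish small-area deprivation data; the matrix is
#' positive definite.
#'
#' @return 6 x 6 correlation matrix with dimnames.
#' @export
deprivation_correlation <- function() {
  v <- c("access", "crime", "education", "employment", "income", "housing")
  S <- diag(6); dimnames(S) <- list(v, v)
  S["access", 2:6] <- c(-0.252, -0.250, -0.287, -0.321, -0.411)
  S["crime", 3:6] <- c(0.411, 0.436, 0.430, 0.351)
  S["education", 4:6] <- c(0.833, 0.860, 0.680)
  S["employment", 5:6] <- c(0.946, 0.436)
  S["income", 6] <- 0.658
  S[lower.tri(S)] <- t(S)[lower.tri(S)]
  S
}

#' Ground truth of a synthetic scenario
#'
#' Parameters under which counts are generated, retained so recovery
#' tests can compare estimates with truth.
#'
#' @param beta length-3 coefficient vector (intercept, exposure,
#'   deprivation).
#' @param rho spatial dependence in [0, 1); the improper rho = 1 limit is
#'   excluded from the generator.
#' @param tau2 random-effect variance scale (> 0).
#' @param seed integer seed.
#' @return object of class \code{scenario_truth}; \code{phi} is filled in
#'   by \code{\link{generate_counts}}.
#' @export
scenario_truth <- function(beta, rho, tau2, seed = 1L) {
  if (length(beta) != 3 || !all(is.finite(beta))) stop("beta must be 3 finite values")
  if (!is.finite(rho) || rho < 0 || rho >= 1)
    stop("generator requires rho in [0, 1): the intrinsic limit is improper")
  if (!is.finite(tau2) || tau2 <= 0) stop("tau2 must be positive")
  structure(list(beta = beta, rho = rho, tau2 = tau2, phi = NULL,
                 seed = as.integer(seed)),
            class = "scenario_truth")
}

#' Generate a zone population table and expected counts
#'
#' Zone populations are drawn uniformly between 500 and 1000 residents
#' (the size band of the small-area geography being emulated) and split
#' across age-sex strata with fixed regional shares; expected counts come
#' from indirect standardisation, \code{E_i = sum_r N_ir * gamma_r}, with
#' region-wide stratum mortality rates \code{gamma_r} (deaths per person
#' over the study period).  Default rates rise steeply with stratum (a
#' caricature of age) and are scaled so that a typical zone's expected
#' count is about 27 deaths over a seven-year window.  Zone age profiles
#' vary: stratum shares are Dirichlet-distributed around the regional
#' profile with concentration \code{age_mixing}, and a fraction
#' \code{young_frac} of zones are city-centre style, with an age profile
#' concentrated on the youngest strata; because the stratum rate ladder
#' is steep (mortality rises roughly 300-fold from the youngest to the
#' oldest stratum), such zones get expected counts of only a few deaths
#' and can realise zero, reproducing the zero-SMR zones seen in real
#' small-area mortality data.
#'
#' @param graph an \code{\link{area_graph}}.
#' @param strata number of age-sex strata (>= 1).
#' @param seed integer seed.
#' @param pop_range zone population bounds.
#' @param gamma optional vector of stratum rates in [0, 1]; default as
#'   described above.
#' @param age_mixing Dirichlet concentration of per-zone stratum shares
#'   around the regional profile (smaller = more demographic contrast).
#' @param young_frac fraction of zones given a young, city-centre style
#'   age profile.
#' @return list with \code{N} (n x strata person counts), \code{gamma},
#'   and \code{E} (length n expected counts).
#' @export
generate_population <- function(graph, strata = 6, seed = 1L,
                                pop_range = c(500, 1000), gamma = NULL,
                                age_mixing = 6, young_frac = 0.03) {
  stopifnot(inherits(graph, "area_graph"), strata >= 1)
  set.seed(seed)
  n <- graph$n
  shares <- seq_len(strata)^0.5
  shares <- shares / sum(shares)
  pop <- round(stats::runif(n, pop_range[1], pop_range[2]))
  if (strata > 1) {
    base <- matrix(rep(shares, each = n), n, strata)
    young <- stats::runif(n) < young_frac
    if (any(young)) {
      yprof <- exp(-(seq_len(strata) - 1))
      base[young, ] <- rep(yprof / sum(yprof), each = sum(young))
    }
    G <- matrix(stats::rgamma(n * strata, shape = age_mixing * strata * base),
                n, strata)
    Wsh <- G / rowSums(G)
  } else {
    Wsh <- matrix(1, n, 1)
  }
  N <- floor(Wsh * pop)
  if (is.null(gamma)) {
    # steep age gradient: ~300-fold from youngest to oldest stratum,
    # anchored so the regional-profile rate is 0.036 deaths/person/period
    raw <- 3.2^(seq_len(strata) - 1)
    target_rate <- 0.036
    gamma <- raw * target_rate / sum(raw * shares)
  }
  if (length(gamma) != strata || any(gamma < 0) || any(gamma > 1))
    stop("gamma must be per-stratum rates in [0, 1]")
  E <- drop(N %*% gamma)
  list(N = N, gamma = gamma, E = E)
}

#' Stratum rates from realised counts
#'
#' Indirect-standardisation closure: computing the region-wide stratum
#' rates from the realised stratum deaths of the same region,
#' \code{gamma_r = sum_i D_ir / sum_i N_ir}, guarantees
#' \code{sum_i E_i = sum_i Y_i} exactly.
#'
#' @param N n x strata person counts.
#' @param deaths n x strata realised death counts.
#' @return vector of stratum rates.
#' @export
rates_from_counts <- function(N, deaths) {
  if (!all(dim(N) == dim(deaths))) stop("N and deaths dimensions differ")
  colSums(deaths) / colSums(N)
}

#' Indirect standardisation
#'
#' @param N n x strata person counts.
#' @param gamma stratum rates.
#' @return expected counts \code{E_i = sum_r N_ir gamma_r}.
#' @export
indirect_standardise <- function(N, gamma) {
  if (ncol(N) != length(gamma)) stop("gamma length must match strata")
  drop(N %*% gamma)
}

#' Generate correlated deprivation domains and a composite index
#'
#' Draws six zone-level Gaussian deprivation domains with a target
#' correlation matrix (default \code{\link{deprivation_correlation}}),
#' so the sample correlations approach the target as n grows (sampling
#' error is of order \code{1/sqrt(n)}; with very few zones the sample
#' correlations are degenerate, e.g. exactly +/-1 at n = 2).  The
#' composite index is the equal-weight mean of the standardised domains,
#' standing in for a re-weighted multiple-deprivation index: the models
#' only require a composite that is correlated with its domains.
#'
#' @param graph an \code{\link{area_graph}}.
#' @param target_corr symmetric positive-definite correlation matrix with
#'   unit diagonal.
#' @param seed integer seed.
#' @return data.frame with columns \code{access, crime, education,
#'   employment, income, housing, simd}.
#' @export
generate_deprivation <- function(graph, target_corr = deprivation_correlation(),
                                 seed = 1L) {
  stopifnot(inherits(graph, "area_graph"))
  d <- ncol(target_corr)
  if (!isTRUE(all.equal(target_corr, t(target_corr))) ||
      !isTRUE(all.equal(diag(target_corr), rep(1, d), check.attributes = FALSE)))
    stop("target_corr must be symmetric with unit diagonal")
  ch <- tryCatch(chol(target_corr),
                 error = function(e) stop("target_corr is not positive definite"))
  set.seed(seed)
  X <- matrix(stats::rnorm(graph$n * d), graph$n, d) %*% ch
  nm <- colnames(target_corr) %||% paste0("domain", seq_len(d))
  colnames(X) <- nm
  df <- as.data.frame(X)
  df$simd <- rowMeans(scale(X))
  df
}

#' Fusion-model emulator settings
#'
#' Generative stand-in for a measurement-calibrated ("fusion") pollution
#' surface: the fusion field is an affine recalibration of the modelled
#' field (\code{alpha[1] + alpha[2] * modelled}) plus a Gaussian-process
#' discrepancy with exponential correlation \code{exp(-d / range_km)},
#' partial sill \code{sigma2} and nugget \code{nu2 * sigma2}.  The
#' modelled field itself is the sum of a smooth conurbation-scale GP
#' (mean \code{mean_level}, sill \code{model_sill}, the same exponential
#' range) and an independent cell-scale component of variance
#' \code{model_nugget} representing kilometre-scale source structure
#' (roads, urban fabric) that a 1 km dispersion map resolves but a smooth
#' trend does not.  Defaults give NO2-like surfaces (mean about 18
#' ug/m^3, zone-level standard deviation about 5, correlation range a few
#' km) whose modelled and fusion versions correlate at about
#' \code{corr_target}.
#'
#' @param alpha length-2 calibration (intercept, slope).
#' @param sigma2 partial sill of the discrepancy GP (>= 0).
#' @param nu2 nugget variance scale (>= 0, as a fraction of sigma2).
#' @param range_km exponential correlation range (> 0), km.
#' @param mean_level,model_sill mean and smooth-component sill of the
#'   modelled field.
#' @param model_nugget cell-scale variance of the modelled field.
#' @param grid_km grid cell spacing, km.
#' @param corr_target,corr_tol the generator's own target band for
#'   cor(modelled, fusion) at the zone level.
#' @return object of class \code{fusion_emulator}.
#' @export
fusion_emulator <- function(alpha = c(0, 1), sigma2 = 4, nu2 = 0.2,
                            range_km = 3, mean_level = 18, model_sill = 16,
                            model_nugget = 18, grid_km = 1,
                            corr_target = 0.9, corr_tol = 0.05) {
  if (sigma2 < 0 || nu2 < 0 || range_km <= 0 || model_sill < 0 ||
      model_nugget < 0)
    stop("variances must be non-negative and the range positive")
  structure(list(alpha = alpha, sigma2 = sigma2, nu2 = nu2,
                 range_km = range_km, mean_level = mean_level,
                 model_sill = model_sill, model_nugget = model_nugget,
                 grid_km = grid_km,
                 corr_target = corr_target, corr_tol = corr_tol),
            class = "fusion_emulator")
}

# GP draw with exponential covariance on given coordinates.
# A degenerate (zero-variance) process returns exact zeros.
gp_draw <- function(x, y, sill, range_km, nugget = 0) {
  n <- length(x)
  if (sill == 0 && nugget == 0) return(numeric(n))
  D <- as.matrix(stats::dist(cbind(x, y)))
  C <- sill * exp(-D / range_km) + diag(nugget + 1e-8 * max(sill, nugget), n)
  drop(crossprod(chol(C), stats::rnorm(n)))
}

#' Generate a pair of zone-level exposure surfaces
#'
#' Simulates a "modelled" (dispersion-model style) gridded NO2 surface and
#' a calibrated "fusion" version, then aggregates both to zones by
#' inverse-exponential-distance weighting
#' (\code{\link{aggregate_grid_to_zones}}).  Grid cells are laid on a
#' regular lattice covering the zone centroids (spacing
#' \code{emulator$grid_km}); zone centroids are jittered off cell centres
#' so that cell-to-zone assignment, weighting and the nearest-cell
#' fallback are all exercised.  Negative cell values (rare at the default
#' mean) are truncated at 0.1.
#'
#' @param graph an \code{\link{area_graph}} with centroids.
#' @param emulator a \code{\link{fusion_emulator}}.
#' @param seed integer seed.
#' @return list with \code{x_modelled}, \code{x_fusion} (length-n zone
#'   exposures), and the two \code{grid_surface}s.
#' @export
generate_exposure_pair <- function(graph, emulator = fusion_emulator(), seed = 1L) {
  stopifnot(inherits(graph, "area_graph"), inherits(emulator, "fusion_emulator"))
  if (is.null(graph$centroids)) stop("graph has no centroids")
  set.seed(seed)
  g <- graph
  g$centroids <- graph$centroids +
    matrix(stats::runif(2 * graph$n, -0.4, 0.4), ncol = 2)
  xr <- range(g$centroids[, 1]); yr <- range(g$centroids[, 2])
  gx <- seq(floor(xr[1]), ceiling(xr[2]), by = emulator$grid_km)
  gy <- seq(floor(yr[1]), ceiling(yr[2]), by = emulator$grid_km)
  cells <- expand.grid(x = gx, y = gy)
  modelled <- emulator$mean_level +
    gp_draw(cells$x, cells$y, emulator$model_sill, emulator$range_km) +
    stats::rnorm(nrow(cells), 0, sqrt(emulator$model_nugget))
  disc <- gp_draw(cells$x, cells$y, emulator$sigma2, emulator$range_km,
                  nugget = emulator$nu2 * emulator$sigma2)
  fusion <- emulator$alpha[1] + emulator$alpha[2] * modelled + disc
  modelled <- pmax(modelled, 0.1)
  fusion <- pmax(fusion, 0.1)
  sm <- assign_cells_to_zones(grid_surface(cells$x, cells$y, modelled), g,
                              max_km = 2 * emulator$grid_km)
  sf <- grid_surface(cells$x, cells$y, fusion, cell_zone = sm$cell_zone)
  list(x_modelled = aggregate_grid_to_zones(sm, g),
       x_fusion = aggregate_grid_to_zones(sf, g),
       surface_modelled = sm, surface_fusion = sf)
}

#' Generate Poisson counts with CAR-structured log-risk
#'
#' Draws the spatial field \code{phi} from the proper Leroux Gaussian
#' with precision \code{(1/tau2)[rho(diag(W1)-W) + (1-rho)I]}, centres it
#' to sum to zero (so the intercept is identified in recovery tests), and
#' simulates \code{Y_i ~ Poisson(E_i exp(z_i' beta + phi_i))}.  The
#' linear predictor is guarded: \code{|eta| > 30} raises an error rather
#' than overflowing.
#'
#' @param E expected counts (positive).
#' @param Z n x 3 design matrix.
#' @param truth a \code{\link{scenario_truth}}.
#' @param graph an \code{\link{area_graph}}.
#' @return list with \code{counts} (a \code{health_counts}: \code{Y},
#'   \code{E}, \code{smr}) and \code{truth} with the realised \code{phi}
#'   filled in.
#' @export
generate_counts <- function(E, Z, truth, graph) {
  stopifnot(inherits(truth, "scenario_truth"), inherits(graph, "area_graph"))
  if (length(E) != graph$n || nrow(Z) != graph$n) stop("dimensions disagree")
  if (any(E <= 0)) stop("E must be positive")
  set.seed(truth$seed)
  Q <- leroux_precision(graph, truth$rho, truth$tau2)$Q
  R <- chol(Q)
  phi <- backsolve(R, stats::rnorm(graph$n))
  phi <- phi - mean(phi)
  eta <- drop(Z %*% truth$beta) + phi
  if (any(abs(eta) > 30))
    stop("linear predictor exceeds overflow guard (|eta| > 30); check scenario scales")
  Y <- stats::rpois(graph$n, E * exp(eta))
  truth$phi <- phi
  counts <- structure(list(Y = Y, E = E, smr = Y / E), class = "health_counts")
  list(counts = counts, truth = truth)
}

#' Default synthetic-study scenario
#'
#' The conditions the generator emulates: 2089 zones on an irregular
#' lattice (a 46 x 46 grid truncated to 2089), six age-sex strata with
#' zone populations of 500-1000, the deprivation correlation structure of
#' \code{\link{deprivation_correlation}}, NO2-like modelled and fusion
#' exposure surfaces, and Poisson counts whose log-risk carries a Leroux
#' field with \code{rho = 0.9}, \code{tau2 = 0.15} (spatially smooth,
#' overdispersed counts).  The true exposure effect defaults to RR 1.011
#' per 5 ug/m^3 on the modelled surface with income as the true
#' deprivation confounder, and the intercept is calibrated so the mean
#' standardised mortality ratio is about 1.066.
#'
#' @param n number of zones.
#' @param rows,cols lattice dimensions (with \code{n <= rows * cols}).
#' @param strata age-sex strata count.
#' @param rho,tau2 true spatial dependence and variance scale.
#' @param rr_true true relative risk per \code{increment} ug/m^3.
#' @param beta3 true deprivation effect (per unit of the covariate).
#' @param target_smr target mean standardised mortality ratio.
#' @param increment RR increment, ug/m^3.
#' @param truth_exposure,truth_deprivation which generated covariates
#'   drive the true risk surface.
#' @param emulator a \code{\link{fusion_emulator}}.
#' @return list of scenario settings consumed by
#'   \code{\link{generate_study}}.
#' @export
default_scenario <- function(n = 2089, rows = ceiling(n / 46), cols = 46,
                             strata = 6, rho = 0.9, tau2 = 0.15,
                             rr_true = 1.011, beta3 = 0.05,
                             target_smr = 1.066, increment = 5,
                             truth_exposure = "modelled",
                             truth_deprivation = "income",
                             emulator = fusion_emulator()) {
  list(n = n, rows = rows, cols = cols, strata = strata, rho = rho,
       tau2 = tau2, rr_true = rr_true, beta3 = beta3,
       target_smr = target_smr, increment = increment,
       truth_exposure = truth_exposure,
       truth_deprivation = truth_deprivation, emulator = emulator)
}

#' Generate a complete synthetic study
#'
#' Runs the whole generator: graph, population and expected counts,
#' correlated deprivation domains plus composite, a modelled/fusion
#' exposure pair, and Poisson counts under a Leroux log-risk field with
#' known ground truth.  The intercept is calibrated against the
#' scenario's target mean SMR given the realised covariates.
#'
#' @param scenario settings from \code{\link{default_scenario}}.
#' @param seed integer master seed (sub-seeds are derived from it).
#' @return object of class \code{synthetic_study}: list with
#'   \code{graph}, \code{zones} (data.frame: label, x_km, y_km, Y, E,
#'   smr, exposure_modelled, exposure_fusion, six domains, simd),
#'   \code{population}, \code{truth}, \code{scenario}.
#' @export
generate_study <- function(scenario = default_scenario(), seed = 1L) {
  seed <- as.integer(seed)
  graph <- build_lattice_graph(scenario$rows, scenario$cols,
                               n_keep = if (scenario$n < scenario$rows * scenario$cols)
                                 scenario$n else NULL)
  pop <- generate_population(graph, scenario$strata, seed = seed + 1L)
  depr <- generate_deprivation(graph, seed = seed + 2L)
  expo <- generate_exposure_pair(graph, scenario$emulator, seed = seed + 3L)
  x <- switch(scenario$truth_exposure,
              modelled = expo$x_modelled, fusion = expo$x_fusion,
              stop("unknown truth_exposure"))
  u <- depr[[scenario$truth_deprivation]]
  beta2 <- beta_for_rr(scenario$rr_true, scenario$increment)
  # intercept calibrated so mean(R) matches the target mean SMR
  beta1 <- log(scenario$target_smr) -
    log(mean(exp(beta2 * x + scenario$beta3 * u))) - scenario$tau2 / 2
  truth <- scenario_truth(c(beta1, beta2, scenario$beta3),
                          scenario$rho, scenario$tau2, seed = seed + 4L)
  Z <- build_design(x, u)
  gen <- generate_counts(pop$E, Z, truth, graph)
  zones <- data.frame(label = graph$labels,
                      x_km = graph$centroids[, 1], y_km = graph$centroids[, 2],
                      Y = gen$counts$Y, E = gen$counts$E, smr = gen$counts$smr,
                      exposure_modelled = expo$x_modelled,
                      exposure_fusion = expo$x_fusion)
  zones <- cbind(zones, depr)
  structure(list(graph = graph, zones = zones, population = pop,
                 truth = gen$truth, scenario = scenario, seed = seed),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("synthetic_study:", x$graph$n, "zones; mean SMR",
      round(mean(x$zones$smr), 3), "\n")
  invisible(x)
}

#' Persist and reload a synthetic study
#'
#' Writes \code{zones.csv} (all zone-level variables), \code{adjacency.gal}
#' and \code{truth.json} into a directory, in the formats the pipeline
#' reads back.
#'
#' @param study a \code{synthetic_study}.
#' @param dir output directory (created if needed).
#' @return \code{read_study} returns a list with \code{graph} and
#'   \code{zones} (plus \code{truth} when present).
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(study$zones, file.path(dir, "zones.csv"), row.names = FALSE)
  write_gal(study$graph, file.path(dir, "adjacency.gal"))
  jsonlite::write_json(
    list(beta = study$truth$beta, rho = study$truth$rho,
         tau2 = study$truth$tau2, seed = study$truth$seed,
         phi = study$truth$phi),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_study
#' @export
read_study <- function(dir) {
  zones <- utils::read.csv(file.path(dir, "zones.csv"))
  graph <- read_gal(file.path(dir, "adjacency.gal"),
                    centroids = as.matrix(zones[, c("x_km", "y_km")]))
  graph$labels <- zones$label
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path))
    jsonlite::read_json(truth_path, simplifyVector = TRUE) else NULL
  list(graph = graph, zones = zones, truth = truth)
}
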