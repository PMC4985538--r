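#' Study configuration
#'
#' Everything needed to run the full sensitivity analysis from data files:
#' the zone table and adjacency, the factor levels of the model grid
#' (exposure versions x deprivation covariates x spatial structures),
#' MCMC and prior settings, the RR increment and a master seed.  The
#' defaults enumerate the 2 x 7 x 3 = 42-model grid: two exposure
#' versions, six deprivation domains plus the composite, and three
#' spatial structures.
#'
#' @param zones_csv,adjacency_gal paths to the study files (may be NULL
#'   when a \code{synthetic_study} object is passed to
#'   \code{\link{run_study}} directly).
#' @param exposures exposure column labels (prefixed \code{exposure_} in
#'   the zone table).
#' @param deprivations deprivation column labels.
#' @param structures spatial structures, subset of
#'   \code{c("glm", "leroux", "os")}.
#' @param mcmc an \code{\link{mcmc_config}}.
#' @param priors a \code{\link{prior_spec}}.
#' @param q eigenvector count for orthogonal smoothing.
#' @param increment RR increment, ug/m^3.
#' @param seed master seed; per-model seeds are derived from it.
#' @param psrf_threshold convergence gate on the exposure coefficient.
#' @param on_nonconverged \code{"fail"} (default) stops the study when a
#'   model misses the gate; \code{"exclude"} drops it from BMA with a log
#'   entry.
#' @return object of class \code{study_config}.
#' @export
study_config <- function(zones_csv = NULL, adjacency_gal = NULL,
                         exposures = c("modelled", "fusion"),
                         deprivations = c("access", "crime", "education",
                                          "employment", "housing", "income",
                                          "simd"),
                         structures = c("glm", "leroux", "os"),
                         mcmc = mcmc_config(), priors = prior_spec(),
                         q = 50, increment = 5, seed = 1,
                         psrf_threshold = 1.05,
                         on_nonconverged = c("fail", "exclude")) {
  if (anyDuplicated(exposures) || anyDuplicated(deprivations) ||
      anyDuplicated(structures))
    stop("duplicate factor labels in the model grid")
  if (!all(structures %in% c("glm", "leroux", "os")))
    stop("structures must be a subset of glm, leroux, os")
  structure(list(zones_csv = zones_csv, adjacency_gal = adjacency_gal,
                 exposures = exposures, deprivations = deprivations,
                 structures = structures, mcmc = mcmc, priors = priors,
                 q = q, increment = increment, seed = as.integer(seed),
                 psrf_threshold = psrf_threshold,
                 on_nonconverged = match.arg(on_nonconverged)),
            class = "study_config")
}

#' Enumerate the model grid
#'
#' Deterministic exposure-major ordering: for each exposure version, for
#' each deprivation covariate, each spatial structure.  The default
#' configuration yields 42 model specifications.
#'
#' @param config a \code{\link{study_config}}.
#' @return list of model specs: \code{index}, \code{exposure},
#'   \code{deprivation}, \code{structure}, \code{q}, \code{label}.
#' @export
enumerate_grid <- function(config) {
  specs <- list()
  k <- 0
  for (e in config$exposures)
    for (d in config$deprivations)
      for (s in config$structures) {
        k <- k + 1
        specs[[k]] <- list(index = as.integer(k), exposure = e, deprivation = d,
                           structure = s,
                           q = if (s == "os") config$q else NULL,
                           label = paste(e, d, s, sep = "/"))
      }
  specs
}

#' Deterministic per-model seed
#'
#' Hashes (master seed, model index) into a positive 32-bit integer so
#' that every model in the grid gets an independent, reproducible seed
#' and results do not depend on execution order.
#'
#' @param master master seed (integer).
#' @param index model index in the grid.
#' @return integer seed.
#' @export
model_seed <- function(master, index) {
  x <- (as.double(master) * 1000003 + as.double(index) * 7919) %% 2147483629
  as.integer(x + 1)
}

#' Fit one model of the grid
#'
#' Resolves a model spec against the zone table and dispatches to the
#' matching sampler.
#'
#' @param spec one element of \code{\link{enumerate_grid}} output.
#' @param zones zone data.frame (columns \code{Y}, \code{E},
#'   \code{exposure_<label>}, deprivation columns).
#' @param graph an \code{\link{area_graph}}.
#' @param config a \code{\link{study_config}}.
#' @return a \code{posterior_draws} object.
#' @export
fit_model_spec <- function(spec, zones, graph, config) {
  xcol <- paste0("exposure_", spec$exposure)
  if (!xcol %in% names(zones)) stop("exposure column not found: ", xcol)
  if (!spec$deprivation %in% names(zones))
    stop("deprivation column not found: ", spec$deprivation)
  Z <- build_design(zones[[xcol]], zones[[spec$deprivation]])
  mc <- config$mcmc
  mc$seed <- model_seed(config$seed, spec$index)
  switch(spec$structure,
         glm = fit_glm(zones$Y, zones$E, Z, config$priors, mc),
         leroux = fit_leroux(zones$Y, zones$E, Z, graph, config$priors, mc),
         os = fit_orthogonal(zones$Y, zones$E, Z, graph, config$priors, mc,
                             q = config$q),
         stop("unknown structure: ", spec$structure))
}

#' Run the full study
#'
#' Fits every model in the grid, assembles the relative-risk table
#' (posterior median RR with 95% interval and a flag for intervals
#' excluding 1), the model-fit table (DIC, effective parameters, RMSE),
#' and combines the exposure effect across converged models by Bayesian
#' model averaging.  Every model uses an independent seed derived from
#' the master seed, so re-running with the same configuration reproduces
#' the outputs exactly.
#'
#' @param study a \code{synthetic_study}, or a list with \code{zones} and
#'   \code{graph} (e.g. from \code{\link{read_study}}); if NULL the data
#'   are read from the paths in \code{config}.
#' @param config a \code{\link{study_config}}.
#' @return object of class \code{study_result}: list with \code{rr_table},
#'   \code{fit_table}, \code{bma} (a \code{bma_result}), \code{log}
#'   (per-model acceptance rates and PSRF), \code{config}.
#' @export
run_study <- function(study = NULL, config = study_config()) {
  if (is.null(study)) {
    zones <- utils::read.csv(config$zones_csv)
    graph <- read_gal(config$adjacency_gal,
                      centroids = as.matrix(zones[, c("x_km", "y_km")]))
  } else {
    zones <- study$zones
    graph <- study$graph
  }
  n <- nrow(zones)
  if (graph$n != n) stop("zone table and adjacency disagree on n")
  specs <- enumerate_grid(config)
  summaries <- vector("list", length(specs))
  logrows <- vector("list", length(specs))
  for (k in seq_along(specs)) {
    spec <- specs[[k]]
    fit <- fit_model_spec(spec, zones, graph, config)
    xcol <- paste0("exposure_", spec$exposure)
    Z <- build_design(zones[[xcol]], zones[[spec$deprivation]])
    s <- summarise_fit(fit, config$increment)
    d <- dic(fit, zones$Y, zones$E, Z)
    r <- psrf(fit)
    converged <- is.finite(r) && r < config$psrf_threshold
    if (!converged && config$on_nonconverged == "fail")
      stop("model ", spec$label, " failed the convergence gate (PSRF = ",
           round(r, 3), ")")
    summaries[[k]] <- c(spec[c("index", "exposure", "deprivation", "structure",
                               "label")],
                        s,
                        list(dic = d$dic, p_d = d$p_d,
                             rmse = rmse(fit, zones$Y, zones$E, Z),
                             logml = log_marginal_likelihood(fit),
                             psrf = r, converged = converged))
    logrows[[k]] <- data.frame(label = spec$label, psrf = r,
                               converged = converged,
                               accept = paste(names(fit$accept),
                                              sprintf("%.2f", unlist(fit$accept)),
                                              sep = "=", collapse = "; "))
    rm(fit)
  }
  rr_table <- do.call(rbind, lapply(summaries, function(s)
    data.frame(exposure = s$exposure, deprivation = s$deprivation,
               structure = s$structure,
               rr = s$rr, rr_lower = s$rr_lower, rr_upper = s$rr_upper,
               excludes_null = s$rr_lower > 1 | s$rr_upper < 1)))
  fit_table <- do.call(rbind, lapply(summaries, function(s)
    data.frame(exposure = s$exposure, deprivation = s$deprivation,
               structure = s$structure,
               dic = s$dic, p_d = s$p_d, rmse = s$rmse)))
  keep <- vapply(summaries, `[[`, logical(1), "converged")
  if (!any(keep)) stop("no model passed the convergence gate")
  bma_res <- bma(lapply(summaries[keep], function(s)
    list(logml = s$logml, beta2_median = s$beta2_median,
         beta2_var = s$beta2_var, p_positive = s$p_positive, rr = s$rr)),
    increment = config$increment,
    labels = vapply(summaries[keep], `[[`, character(1), "label"))
  structure(list(rr_table = rr_table, fit_table = fit_table,
                 bma = bma_res,
                 summaries = summaries,
                 log = do.call(rbind, logrows),
                 config = config),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat("study_result:", nrow(x$rr_table), "models;",
      sum(x$rr_table$excludes_null), "intervals exclude RR = 1\n")
  print(x$bma)
  invisible(x)
}

#' Write study tables
#'
#' Emits the relative-risk table and the model-fit table as CSV (3
#' decimal places on the RR scale) and the BMA report (CSV + JSON) into a
#' directory.
#'
#' @param result a \code{study_result}.
#' @param dir output directory (created if needed).
#' @export
write_study_tables <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rr <- result$rr_table
  rr$rr <- round(rr$rr, 3); rr$rr_lower <- round(rr$rr_lower, 3)
  rr$rr_upper <- round(rr$rr_upper, 3)
  utils::write.csv(rr, file.path(dir, "relative_risks.csv"), row.names = FALSE)
  ft <- result$fit_table
  ft$dic <- round(ft$dic, 1); ft$p_d <- round(ft$p_d, 1)
  ft$rmse <- round(ft$rmse, 3)
  utils::write.csv(ft, file.path(dir, "model_fit.csv"), row.names = FALSE)
  write_bma_report(result$bma, file.path(dir, "bma_report"))
  utils::write.csv(result$log, file.path(dir, "run_log.csv"), row.names = FALSE)
  invisible(dir)
}
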