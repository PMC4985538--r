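#' Gridded pollution surface
#'
#' A regular (or arbitrary) set of grid cells carrying pollutant
#' concentrations, e.g. annual-mean NO2 at 1 km resolution.  Each cell may
#' be assigned to the zone containing its centroid; cells falling in no
#' zone have assignment \code{NA}.
#'
#' @param x_km,y_km planar cell-centroid coordinates in km.
#' @param values concentration per cell (finite, >= 0), ug/m^3.
#' @param cell_zone optional integer vector assigning each cell to a zone
#'   (1-based) or \code{NA}; if omitted it can be filled in later with
#'   \code{\link{assign_cells_to_zones}}.
#' @return object of class \code{grid_surface}.
#' @export
grid_surface <- function(x_km, y_km, values, cell_zone = NULL) {
  if (length(x_km) != length(values) || length(y_km) != length(values))
    stop("coordinate and value lengths differ")
  if (length(values) == 0) stop("empty surface")
  if (!all(is.finite(x_km)) || !all(is.finite(y_km)))
    stop("coordinates must be finite")
  if (!all(is.finite(values)) || any(values < 0))
    stop("values must be finite and non-negative")
  structure(list(x_km = as.numeric(x_km), y_km = as.numeric(y_km),
                 values = as.numeric(values), cell_zone = cell_zone),
            class = "grid_surface")
}

#' Assign grid cells to zones by nearest centroid
#'
#' Stands in for point-in-polygon containment when only zone centroids are
#' available: each cell is assigned to the zone whose centroid is nearest,
#' provided that distance is at most \code{max_km} (otherwise \code{NA},
#' i.e. the cell lies outside the study region).  Ties go to the lowest
#' zone index.
#'
#' @param surface a \code{grid_surface}.
#' @param graph an \code{\link{area_graph}} with centroids.
#' @param max_km assignment radius, km.
#' @return the surface with \code{cell_zone} filled in.
#' @export
assign_cells_to_zones <- function(surface, graph, max_km = Inf) {
  stopifnot(inherits(surface, "grid_surface"), inherits(graph, "area_graph"))
  if (is.null(graph$centroids)) stop("graph has no centroids")
  cz <- integer(length(surface$values))
  for (k in seq_along(cz)) {
    d <- sqrt((graph$centroids[, 1] - surface$x_km[k])^2 +
              (graph$centroids[, 2] - surface$y_km[k])^2)
    i <- which.min(d)  # ties -> lowest index
    cz[k] <- if (d[i] <= max_km) i else NA_integer_
  }
  surface$cell_zone <- cz
  surface
}

#' Aggregate a gridded surface to zone-level exposures
#'
#' Implements inverse-exponential-distance averaging of grid-cell
#' concentrations to each zone: with \eqn{d_{ij}} the Euclidean distance
#' (km) between the (population-weighted) centroid of zone \eqn{i} and the
#' centroid of grid cell \eqn{j}, the zone value is
#' \deqn{x_i = \frac{\sum_j \exp(-d_{ij}) \tilde v_j}{\sum_j \exp(-d_{ij})}}
#' over the cells assigned to zone \eqn{i}.  The weights are convex, so
#' the result always lies within the range of the contributing cell
#' values.  A zone containing no cell centroid is assigned the value of
#' the cell nearest its centroid (distance ties broken by lowest cell
#' index).  Distances are in km throughout (the weight \eqn{e^{-d}} is
#' unit-dependent; the package records \code{distance_unit_km = TRUE}).
#'
#' @param surface a \code{grid_surface}; if \code{cell_zone} is missing it
#'   is filled by \code{\link{assign_cells_to_zones}}.
#' @param graph an \code{\link{area_graph}} with centroids.
#' @return numeric vector of length n (zone exposures, ug/m^3).
#' @export
aggregate_grid_to_zones <- function(surface, graph) {
  stopifnot(inherits(surface, "grid_surface"), inherits(graph, "area_graph"))
  if (is.null(graph$centroids)) stop("graph has no centroids")
  if (is.null(surface$cell_zone)) surface <- assign_cells_to_zones(surface, graph)
  out <- numeric(graph$n)
  for (i in seq_len(graph$n)) {
    cx <- graph$centroids[i, 1]; cy <- graph$centroids[i, 2]
    cells <- which(!is.na(surface$cell_zone) & surface$cell_zone == i)
    if (length(cells) > 0) {
      d <- sqrt((surface$x_km[cells] - cx)^2 + (surface$y_km[cells] - cy)^2)
      w <- exp(-d)
      out[i] <- sum(w * surface$values[cells]) / sum(w)
    } else {
      d <- sqrt((surface$x_km - cx)^2 + (surface$y_km - cy)^2)
      out[i] <- surface$values[which.min(d)]  # ties -> lowest cell index
    }
  }
  out
}

#' Average a list of yearly surfaces
#'
#' Temporal aggregation before spatial aggregation: cellwise mean of
#' several surfaces defined on the same grid.
#'
#' @param surfaces list of \code{grid_surface} objects on identical cells.
#' @return a single \code{grid_surface} of cellwise means.
#' @export
average_surfaces <- function(surfaces) {
  stopifnot(length(surfaces) >= 1)
  s1 <- surfaces[[1]]
  for (s in surfaces[-1]) {
    if (!isTRUE(all.equal(s$x_km, s1$x_km)) || !isTRUE(all.equal(s$y_km, s1$y_km)))
      stop("surfaces are not on the same grid")
  }
  vals <- rowMeans(vapply(surfaces, `[[`, numeric(length(s1$values)), "values"))
  grid_surface(s1$x_km, s1$y_km, vals, cell_zone = s1$cell_zone)
}

#' Relative risk per exposure increment
#'
#' Converts a log-linear regression coefficient to the relative-risk scale
#' for a fixed increment of exposure (default 5 ug/m^3, a realistic change
#' in long-term NO2): \code{RR = exp(increment * beta2)}.
#' \code{beta_for_rr} is the inverse transform.
#'
#' @param beta2 regression coefficient on the exposure (per ug/m^3).
#' @param rr relative risk per increment.
#' @param increment exposure increment, ug/m^3.
#' @return \code{rr_per_increment}: the relative risk;
#'   \code{beta_for_rr}: the coefficient.
#' @examples
#' rr_per_increment(log(2) / 5)        # 2
#' beta_for_rr(1.011)                  # ln(1.011)/5
#' @export
rr_per_increment <- function(beta2, increment = 5) {
  if (!all(is.finite(beta2))) stop("beta2 must be finite")
  exp(increment * beta2)
}

#' @rdname rr_per_increment
#' @export
beta_for_rr <- function(rr, increment = 5) {
  if (!all(is.finite(rr)) || any(rr <= 0)) stop("rr must be finite and positive")
  log(rr) / increment
}

#' Read and write exposure tables
#'
#' Grid CSV columns: \code{cell_id, x_km, y_km, value}; zone exposure CSV
#' columns: \code{zone_id, exposure}.
#' @param path file path.
#' @param surface a \code{grid_surface}; \code{exposure} a numeric vector.
#' @param exposure numeric vector of zone exposures.
#' @export
read_grid_csv <- function(path) {
  df <- utils::read.csv(path)
  df <- df[order(df$cell_id), ]
  grid_surface(df$x_km, df$y_km, df$value)
}

#' @rdname read_grid_csv
#' @export
write_grid_csv <- function(surface, path) {
  utils::write.csv(data.frame(cell_id = seq_along(surface$values),
                              x_km = surface$x_km, y_km = surface$y_km,
                              value = surface$values),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_grid_csv
#' @export
write_zone_exposure_csv <- function(exposure, path) {
  utils::write.csv(data.frame(zone_id = seq_along(exposure), exposure = exposure),
                   path, row.names = FALSE)
  invisible(path)
}
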