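#' Areal adjacency graph
#'
#' An \code{area_graph} describes the neighbourhood structure of a set of
#' \code{n} small areas ("zones"): a binary symmetric adjacency matrix
#' \code{W} whose entry \code{w_ij = 1} indicates that zones \code{i} and
#' \code{j} share a border, optional planar centroid coordinates in km, and
#' zone labels.  Every spatial model and diagnostic in the package takes
#' one of these objects.
#'
#' Zones with no neighbours ("islands") are rejected at validation: the CAR
#' full conditionals are defined through neighbour sums and an island would
#' silently change the meaning of the prior, so the package fails loudly
#' instead.
#'
#' @param W n x n binary symmetric adjacency matrix with zero diagonal.
#' @param centroids optional n x 2 numeric matrix of planar coordinates (km).
#' @param labels optional character vector of zone identifiers.
#' @return An object of class \code{area_graph}: a list with elements
#'   \code{n}, \code{W}, \code{centroids}, \code{labels}, \code{degree}
#'   (row sums of \code{W}) and \code{edges} (two-column matrix of each
#'   undirected edge once, \code{i < j}).
#' @export
area_graph <- function(W, centroids = NULL, labels = NULL) {
  W <- as.matrix(W)
  n <- nrow(W)
  if (ncol(W) != n) stop("W must be square")
  if (!all(W %in% c(0, 1))) stop("W entries must be 0 or 1")
  if (any(diag(W) != 0)) stop("W must have a zero diagonal")
  if (!isTRUE(all.equal(W, t(W)))) stop("W must be symmetric")
  degree <- rowSums(W)
  if (any(degree == 0)) {
    stop("island zones (no neighbours) detected at positions: ",
         paste(which(degree == 0), collapse = ", "))
  }
  if (is.null(labels)) labels <- sprintf("z%04d", seq_len(n))
  if (!is.null(centroids)) {
    centroids <- as.matrix(centroids)
    if (nrow(centroids) != n || ncol(centroids) != 2)
      stop("centroids must be an n x 2 matrix")
    if (!all(is.finite(centroids))) stop("centroids must be finite")
  }
  ut <- which(upper.tri(W) & W == 1, arr.ind = TRUE)
  edges <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
  colnames(edges) <- c("i", "j")
  structure(list(n = n, W = W, centroids = centroids, labels = labels,
                 degree = degree, edges = edges),
            class = "area_graph")
}

#' @export
print.area_graph <- function(x, ...) {
  cat("area_graph:", x$n, "zones,", nrow(x$edges), "edges",
      if (is.null(x$centroids)) "(no centroids)" else "", "\n")
  invisible(x)
}

#' Rook-adjacency lattice graph
#'
#' Builds a regular \code{rows} x \code{cols} lattice in which each zone
#' neighbours the zones immediately above, below, left and right of it.
#' Centroids are placed on a unit (1 km) grid, row-major.  Optionally only
#' the first \code{n_keep} zones (row-major order) are kept, which yields
#' an irregular but still connected graph; this is how the generator
#' produces study regions whose size is not a product of two integers.
#'
#' @param rows,cols positive integers; \code{rows * cols >= 2}.
#' @param n_keep optional; keep only the first \code{n_keep} zones in
#'   row-major order (\code{cols < n_keep <= rows*cols} so the result stays
#'   connected).
#' @return An \code{area_graph}.
#' @examples
#' g <- build_lattice_graph(3, 3)
#' g$degree
#' @export
build_lattice_graph <- function(rows, cols, n_keep = NULL) {
  if (rows < 1 || cols < 1 || rows * cols < 2)
    stop("rows and cols must be positive with rows*cols >= 2")
  n_full <- rows * cols
  idx <- function(r, c) (r - 1) * cols + c
  W <- matrix(0, n_full, n_full)
  for (r in seq_len(rows)) {
    for (c in seq_len(cols)) {
      i <- idx(r, c)
      if (c < cols) W[i, idx(r, c + 1)] <- W[idx(r, c + 1), i] <- 1
      if (r < rows) W[i, idx(r + 1, c)] <- W[idx(r + 1, c), i] <- 1
    }
  }
  cent <- cbind(x_km = rep(seq_len(cols), times = rows),
                y_km = rep(seq_len(rows), each = cols))
  if (!is.null(n_keep)) {
    if (n_keep > n_full || n_keep <= cols)
      stop("n_keep must satisfy cols < n_keep <= rows*cols")
    keep <- seq_len(n_keep)
    W <- W[keep, keep, drop = FALSE]
    cent <- cent[keep, , drop = FALSE]
  }
  area_graph(W, centroids = cent)
}

#' Read and write GAL neighbour files
#'
#' The GAL dialect used here is: a header line giving the number of zones,
#' then for each zone two lines, \code{"<id> <k>"} followed by the ids of
#' its \code{k} neighbours.  Ids in the file are 1-based zone indices;
#' internally zones are addressed by position.
#'
#' @param path file path.
#' @param graph an \code{area_graph} (for writing).
#' @param centroids optional n x 2 matrix to attach when reading.
#' @return \code{read_gal} returns an \code{area_graph};
#'   \code{write_gal} returns \code{path} invisibly.
#' @export
read_gal <- function(path, centroids = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  n <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]][1])
  W <- matrix(0, n, n)
  pos <- 2
  for (k in seq_len(n)) {
    hdr <- as.integer(strsplit(trimws(lines[pos]), "\\s+")[[1]])
    i <- hdr[1]; deg <- hdr[2]
    nb <- if (deg > 0) as.integer(strsplit(trimws(lines[pos + 1]), "\\s+")[[1]]) else integer(0)
    if (length(nb) != deg) stop("GAL record for zone ", i, " lists ", length(nb),
                                " neighbours, header says ", deg)
    W[i, nb] <- 1
    pos <- pos + 2
  }
  if (!isTRUE(all.equal(W, t(W)))) stop("GAL file describes an asymmetric adjacency")
  area_graph(W, centroids = centroids)
}

#' @rdname read_gal
#' @export
write_gal <- function(graph, path) {
  stopifnot(inherits(graph, "area_graph"))
  out <- character(1 + 2 * graph$n)
  out[1] <- as.character(graph$n)
  for (i in seq_len(graph$n)) {
    nb <- which(graph$W[i, ] == 1)
    out[2 * i] <- paste(i, length(nb))
    out[2 * i + 1] <- paste(nb, collapse = " ")
  }
  writeLines(out, path)
  invisible(path)
}

#' Read and write CSV edge lists
#'
#' Alternative adjacency dialect: a CSV with columns \code{zone_i, zone_j},
#' one row per undirected edge (1-based indices).
#'
#' @param path file path.
#' @param n number of zones (needed when reading, since isolated trailing
#'   zones cannot be inferred from edges alone).
#' @param graph an \code{area_graph} (for writing).
#' @param centroids optional n x 2 centroid matrix attached when reading.
#' @return \code{read_edge_csv} returns an \code{area_graph}.
#' @export
read_edge_csv <- function(path, n, centroids = NULL) {
  df <- utils::read.csv(path)
  W <- matrix(0, n, n)
  for (r in seq_len(nrow(df))) {
    i <- df$zone_i[r]; j <- df$zone_j[r]
    W[i, j] <- W[j, i] <- 1
  }
  area_graph(W, centroids = centroids)
}

#' @rdname read_edge_csv
#' @export
write_edge_csv <- function(graph, path) {
  stopifnot(inherits(graph, "area_graph"))
  utils::write.csv(data.frame(zone_i = graph$edges[, "i"],
                              zone_j = graph$edges[, "j"]),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read zone centroids from CSV
#'
#' Columns: \code{zone_id, x_km, y_km}; rows are sorted by \code{zone_id}.
#' @param path file path.
#' @return n x 2 matrix of coordinates in km.
#' @export
read_centroids_csv <- function(path) {
  df <- utils::read.csv(path)
  df <- df[order(df$zone_id), ]
  m <- as.matrix(df[, c("x_km", "y_km")])
  rownames(m) <- NULL
  m
}
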