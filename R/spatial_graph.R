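#' Spatially embedded binary graph
#'
#' The basic container used throughout the package: a binary, undirected,
#' zero-diagonal adjacency matrix together with 3-D node coordinates in
#' millimetres.  All modelling targets, seeds and simulated networks are
#' `spatial_graph` objects.
#'
#' @param adjacency square numeric/integer matrix with entries in `{0, 1}`,
#'   symmetric, zero diagonal.
#' @param coordinates an `n x 3` matrix or a data frame with columns
#'   `x`, `y`, `z` (mm).
#' @param labels optional character vector of node names.
#'
#' @return An object of class `spatial_graph`.
#' @examples
#' coords <- generate_coordinates(10, rng_seed = 1)
#' a <- matrix(0, 10, 10); a[1, 2] <- a[2, 1] <- 1
#' g <- spatial_graph(a, coords)
#' edge_count(g)
#' @export
spatial_graph <- function(adjacency, coordinates, labels = NULL) {
  adjacency <- as.matrix(adjacency)
  if (nrow(adjacency) != ncol(adjacency))
    abort("`adjacency` must be square.")
  n <- nrow(adjacency)
  coordinates <- as_coord_matrix(coordinates)
  if (nrow(coordinates) != n)
    abort("`coordinates` must have one row per node.")
  if (!all(adjacency %in% c(0, 1)))
    abort("`adjacency` entries must be 0 or 1.")
  if (any(diag(adjacency) != 0))
    abort("`adjacency` must have a zero diagonal.")
  if (!isTRUE(all.equal(adjacency, t(adjacency))))
    abort("`adjacency` must be symmetric.")
  storage.mode(adjacency) <- "integer"
  if (!is.null(labels)) stopifnot(length(labels) == n)
  dimnames(adjacency) <- if (is.null(labels)) NULL else list(labels, labels)
  rownames(coordinates) <- NULL
  structure(list(adjacency = adjacency, coordinates = coordinates,
                 labels = labels),
            class = "spatial_graph")
}

as_coord_matrix <- function(coordinates) {
  if (is.data.frame(coordinates)) {
    stopifnot(all(c("x", "y", "z") %in% names(coordinates)))
    coordinates <- as.matrix(coordinates[, c("x", "y", "z")])
  }
  coordinates <- as.matrix(coordinates)
  if (ncol(coordinates) != 3) abort("coordinates must be n x 3 (x, y, z in mm).")
  storage.mode(coordinates) <- "double"
  colnames(coordinates) <- c("x", "y", "z")
  coordinates
}

#' @export
print.spatial_graph <- function(x, ...) {
  cat(sprintf("<spatial_graph> %d nodes, %d edges (density %.4f)\n",
              n_nodes(x), edge_count(x), graph_density(x)))
  invisible(x)
}

#' Node, edge and density accessors
#'
#' @param graph a [spatial_graph()].
#' @return `n_nodes()` the node count; `edge_count()` the undirected edge
#'   count; `graph_density()` edges divided by `n(n-1)/2`.
#' @export
n_nodes <- function(graph) nrow(graph$adjacency)

#' @rdname n_nodes
#' @export
edge_count <- function(graph) sum(graph$adjacency) %/% 2L

#' @rdname n_nodes
#' @export
graph_density <- function(graph) {
  n <- n_nodes(graph)
  edge_count(graph) / (n * (n - 1) / 2)
}

#' Euclidean inter-node distance matrix of a graph or coordinate table
#'
#' @param x a [spatial_graph()] or a coordinate table (`n x 3` matrix or a
#'   data frame with `x`, `y`, `z`).
#' @return dense `n x n` matrix of straight-line distances (mm).
#' @export
distance_matrix <- function(x) {
  coords <- if (inherits(x, "spatial_graph")) x$coordinates else as_coord_matrix(x)
  as.matrix(dist(coords))
}

#' Edge table of a spatial graph
#'
#' @param graph a [spatial_graph()].
#' @return tibble with columns `from`, `to` (node indices, `from < to`) and
#'   `length` (mm).
#' @export
edge_table <- function(graph) {
  idx <- which(upper.tri(graph$adjacency) & graph$adjacency == 1L, arr.ind = TRUE)
  d <- distance_matrix(graph)
  tibble::tibble(from = idx[, 1], to = idx[, 2], length = d[idx])
}

#' Convert to an igraph object
#'
#' @param graph a [spatial_graph()].
#' @return an undirected [igraph::graph] with the same node order.
#' @export
as_igraph <- function(graph) {
  igraph::graph_from_adjacency_matrix(graph$adjacency, mode = "undirected")
}

# linear upper-triangle index of the edge set; used for fast set comparisons
edge_index_set <- function(graph) {
  which(graph$adjacency[upper.tri(graph$adjacency)] == 1L)
}

# rebuild a spatial_graph from an adjacency matrix, reusing geometry
rewrap_graph <- function(adjacency, template) {
  spatial_graph(adjacency, template$coordinates, template$labels)
}
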