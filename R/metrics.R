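#' Local (nodal) graph metrics
#'
#' The six per-node statistics used by the topological fingerprint and the
#' model-fit energy: degree, clustering, betweenness-centrality
#' (unnormalised shortest-path counts), mean incident edge length (mm),
#' local efficiency, and eigenvector centrality (unit Euclidean norm).
#' Isolated nodes receive clustering 0, local efficiency 0 and mean edge
#' length 0.
#'
#' @param graph a [spatial_graph()].
#' @return tibble with columns `node`, `degree`, `clustering`,
#'   `betweenness`, `edge_length`, `local_efficiency`,
#'   `eigenvector_centrality`.
#' @export
nodal_metrics <- function(graph) {
  n <- n_nodes(graph)
  deg <- rowSums(graph$adjacency)
  if (edge_count(graph) == 0) {
    return(tibble::tibble(node = seq_len(n), degree = 0, clustering = 0,
                          betweenness = 0, edge_length = 0,
                          local_efficiency = 0, eigenvector_centrality = 0))
  }
  ig <- as_igraph(graph)
  clust <- igraph::transitivity(ig, type = "localundirected", isolates = "zero")
  btw <- igraph::betweenness(ig, directed = FALSE, normalized = FALSE)
  leff <- igraph::local_efficiency(ig, directed = FALSE)
  leff[!is.finite(leff)] <- 0
  ev <- igraph::eigen_centrality(ig)$vector
  nrm <- sqrt(sum(ev^2))
  if (nrm > 0) ev <- ev / nrm
  d <- distance_matrix(graph)
  elen <- rowSums(d * graph$adjacency)
  elen <- ifelse(deg > 0, elen / deg, 0)
  tibble::tibble(node = seq_len(n), degree = deg, clustering = clust,
                 betweenness = btw, edge_length = elen,
                 local_efficiency = leff, eigenvector_centrality = ev)
}

#' Global graph metrics
#'
#' Modularity Q of a Louvain partition (fixed internal seed), degree
#' assortativity, global clustering (transitivity), and global efficiency
#' (mean inverse shortest-path length over node pairs; disconnected pairs
#' contribute 0).
#'
#' @param graph a [spatial_graph()].
#' @return one-row tibble `modularity`, `assortativity`,
#'   `global_clustering`, `global_efficiency`.
#' @export
global_metrics <- function(graph) {
  if (edge_count(graph) == 0) {
    return(tibble::tibble(modularity = NA_real_, assortativity = NA_real_,
                          global_clustering = 0, global_efficiency = 0))
  }
  ig <- as_igraph(graph)
  comm <- withr::with_seed(1L, igraph::cluster_louvain(ig))
  tibble::tibble(
    modularity = igraph::modularity(ig, igraph::membership(comm)),
    assortativity = igraph::assortativity_degree(ig),
    global_clustering = igraph::transitivity(ig, type = "global"),
    global_efficiency = global_efficiency(graph))
}

#' Global efficiency of a binary graph
#'
#' Mean of inverse shortest-path lengths over all unordered node pairs,
#' with unreachable pairs contributing 0 (the `1/Inf` convention).
#'
#' @param graph a [spatial_graph()].
#' @return value in `[0, 1]`.
#' @export
global_efficiency <- function(graph) {
  n <- n_nodes(graph)
  if (n < 2) return(0)
  if (edge_count(graph) == 0) return(0)
  sp <- igraph::distances(as_igraph(graph))
  inv <- 1 / sp[upper.tri(sp)]
  inv[!is.finite(inv)] <- 0
  mean(inv)
}

#' Coefficient of variation of a nodal metric across participants
#'
#' Sample-SD convention (`sd(x)/mean(x)` per node).  Nodes with mean 0 are
#' flagged undefined (`NA`), never infinite.
#'
#' @param metric_matrix participants x nodes numeric matrix.
#' @return tibble with columns `node` and `cv`.
#' @export
coefficient_of_variation <- function(metric_matrix) {
  metric_matrix <- as.matrix(metric_matrix)
  if (nrow(metric_matrix) < 2)
    abort("need at least 2 participants to compute a CV.")
  mu <- colMeans(metric_matrix)
  s <- apply(metric_matrix, 2, sd)
  cv <- ifelse(mu == 0, NA_real_, s / mu)
  tibble::tibble(node = seq_len(ncol(metric_matrix)), cv = cv)
}
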