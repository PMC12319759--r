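#' Weighted connectome stack
#'
#' A participants x n x n array of non-negative streamline counts; every
#' participant slice must be symmetric with a zero diagonal.
#'
#' @param weights 3-D numeric array (participant, node, node) or a list of
#'   n x n matrices.
#' @return a validated `weighted_stack` (3-D array).
#' @export
weighted_stack <- function(weights) {
  if (is.list(weights)) {
    n <- nrow(weights[[1]])
    arr <- array(0, dim = c(length(weights), n, n))
    for (p in seq_along(weights)) arr[p, , ] <- as.matrix(weights[[p]])
    weights <- arr
  }
  if (length(dim(weights)) != 3 || dim(weights)[2] != dim(weights)[3])
    abort("`weights` must be a participants x n x n array.")
  if (dim(weights)[1] < 1) abort("empty stack.")
  if (any(weights < 0)) abort("streamline counts must be non-negative.")
  for (p in seq_len(dim(weights)[1])) {
    sl <- weights[p, , ]
    if (any(diag(sl) != 0) || !isTRUE(all.equal(sl, t(sl))))
      abort(sprintf("slice %d is not symmetric with zero diagonal.", p))
  }
  structure(weights, class = c("weighted_stack", "array"))
}

n_participants <- function(stack) dim(stack)[1]

#' Prevalence threshold on a weighted stack
#'
#' Retains, across all participants, only the connections whose nonzero
#' count across participants reaches `ceiling(prevalence * participants)`;
#' surviving connections keep their weights, all others are zeroed for
#' every participant.
#'
#' @param stack a [weighted_stack()].
#' @param prevalence fraction in (0, 1]; e.g. `0.60` keeps connections
#'   common to at least 60% of participants.
#' @return a [weighted_stack()] with the same dimensions.
#' @export
prevalence_threshold <- function(stack, prevalence) {
  stack <- weighted_stack(unclass(stack))
  if (prevalence <= 0 || prevalence > 1)
    abort("`prevalence` must lie in (0, 1].")
  p <- n_participants(stack)
  counts <- apply(stack > 0, c(2, 3), sum)
  keep <- counts >= ceiling(prevalence * p)
  out <- unclass(stack)
  for (s in seq_len(p)) out[s, , ] <- out[s, , ] * keep
  weighted_stack(out)
}

#' Distance-dependent consensus network
#'
#' Builds a single binary group target whose edge count matches the mean
#' participant edge count and whose edge-length distribution tracks the
#' participants'.  Candidate edges are binned into `n_bins` equal-frequency
#' length bins; each bin receives a quota equal to the mean number of
#' participant edges falling in it, filled by the most prevalent edges
#' (ties broken by higher mean weight, then lexicographic node index).
#'
#' @param stack a [weighted_stack()], typically already prevalence-thresholded.
#' @param coordinates coordinate table for the nodes.
#' @param n_bins number of equal-frequency length bins (default 10).
#' @return a [spatial_graph()] consensus network.
#' @export
distance_dependent_consensus <- function(stack, coordinates, n_bins = 10) {
  stack <- weighted_stack(unclass(stack))
  if (n_bins < 1) abort("`n_bins` must be at least 1.")
  coords <- as_coord_matrix(coordinates)
  n <- dim(stack)[2]
  if (nrow(coords) != n) abort("`coordinates` must have one row per node.")
  d <- as.matrix(dist(coords))
  p <- n_participants(stack)

  ut <- upper.tri(d)
  idx <- which(ut, arr.ind = TRUE)
  counts <- apply(stack > 0, c(2, 3), sum)[ut]
  meanw <- apply(stack, c(2, 3), mean)[ut]
  len <- d[ut]

  cand <- which(counts > 0)
  if (length(cand) == 0) abort("stack has no connections.")
  target <- round(mean(apply(stack > 0, 1, function(sl) sum(sl[ut]))))

  breaks <- unique(quantile(len[cand], probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(len[cand], breaks = breaks, include.lowest = TRUE)
  # per-participant mean edge count per bin sets the quota
  adj <- matrix(0L, n, n)
  kept_total <- 0L
  for (b in levels(bin)) {
    in_bin <- cand[bin == b]
    if (length(in_bin) == 0) {
      warn(sprintf("length bin %s has no candidate edges; skipped.", b))
      next
    }
    quota <- round(sum(counts[in_bin]) / p)
    quota <- min(quota, length(in_bin))
    if (quota < 1) next
    ord <- order(-counts[in_bin], -meanw[in_bin],
                 idx[in_bin, 1], idx[in_bin, 2])
    keep <- in_bin[ord[seq_len(quota)]]
    adj[idx[keep, , drop = FALSE]] <- 1L
    kept_total <- kept_total + quota
  }
  spatial_graph(adj + t(adj), coords)
}

#' Binarise a weighted connectome at a streamline-count threshold
#'
#' @param weights symmetric non-negative n x n weight matrix.
#' @param threshold minimum streamline count for an edge (a weight exactly
#'   at the threshold is retained); at `threshold = 0` the binarised
#'   support of the matrix is returned.
#' @param coordinates coordinate table for the nodes.
#' @return a [spatial_graph()].
#' @export
streamline_threshold <- function(weights, threshold, coordinates) {
  weights <- as.matrix(weights)
  if (any(weights < 0)) abort("weights must be non-negative.")
  if (threshold < 0) abort("`threshold` must be non-negative.")
  adj <- (weights >= threshold & weights > 0) * 1L
  diag(adj) <- 0L
  spatial_graph(adj, coordinates)
}

#' Seed network from a stack of binary graphs
#'
#' The common starting point of all simulations: connections present in at
#' least `prevalence` of the participant graphs.
#'
#' @param graphs list of [spatial_graph()]s sharing a node set.
#' @param prevalence fraction in (0, 1]; the empirical pipeline uses .95.
#' @return a [spatial_graph()]; an empty seed is allowed (with a warning).
#' @export
seed_network <- function(graphs, prevalence = 0.95) {
  stopifnot(length(graphs) >= 1)
  n <- n_nodes(graphs[[1]])
  if (!all(vapply(graphs, n_nodes, 1L) == n))
    abort("all graphs must share the node set.")
  counts <- Reduce(`+`, lapply(graphs, function(g) g$adjacency))
  adj <- (counts >= ceiling(prevalence * length(graphs))) * 1L
  g <- spatial_graph(adj, graphs[[1]]$coordinates, graphs[[1]]$labels)
  if (edge_count(g) == 0)
    warn("seed network is empty; simulations will start from no edges.")
  message(sprintf("seed network density: %.4f (%d edges)",
                  graph_density(g), edge_count(g)))
  g
}
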