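#' Two-sample Kolmogorov-Smirnov statistic
#'
#' The supremum of the absolute difference between the two empirical CDFs,
#' used descriptively (no p-value) as a distributional distance.
#'
#' @param sample_a,sample_b non-empty numeric vectors.
#' @return value in `[0, 1]`.
#' @export
ks_statistic <- function(sample_a, sample_b) {
  na <- length(sample_a); nb <- length(sample_b)
  if (na == 0 || nb == 0) abort("both samples must be non-empty.")
  pooled <- c(sample_a, sample_b)
  o <- order(pooled)
  # running ECDF difference, evaluated at the last of tied values; values
  # within relative 1e-9 count as tied so float summation noise cannot
  # split a genuine tie (betweenness sums differ across evaluation orders)
  sorted <- pooled[o]
  steps <- cumsum(ifelse(o <= na, 1 / na, -1 / nb))
  gaps <- diff(sorted) > 1e-9 * pmax(1, abs(sorted[-1]))
  max(abs(steps[c(gaps, TRUE)]))
}

# the four energy statistics of a graph; degree/clustering/betweenness are
# nodal distributions, edge length is per existing edge
energy_stats <- function(graph, d = NULL) {
  if (is.null(d)) d <- distance_matrix(graph)
  deg <- rowSums(graph$adjacency)
  ig <- as_igraph(graph)
  list(degree = deg,
       clustering = igraph::transitivity(ig, type = "localundirected",
                                         isolates = "zero"),
       betweenness = igraph::betweenness(ig, directed = FALSE),
       edge_length = d[upper.tri(d) & graph$adjacency == 1L])
}

#' Model-fit energy between a simulated and an empirical network
#'
#' The maximum of four two-sample KS statistics comparing the simulated
#' and empirical distributions of nodal degree, nodal clustering, nodal
#' betweenness-centrality, and edge length: `E = max(KSk, KSc, KSb, KSe)`.
#'
#' @param simulated,empirical [spatial_graph()]s on the same node set and
#'   coordinates, each with at least one edge.
#' @param empirical_stats optional precomputed stats for `empirical`
#'   (internal fast path for grid searches).
#' @return one-row tibble `ks_degree`, `ks_clustering`, `ks_betweenness`,
#'   `ks_edge_length`, `energy`.
#' @export
energy <- function(simulated, empirical, empirical_stats = NULL) {
  if (edge_count(simulated) == 0 ||
      (is.null(empirical_stats) && edge_count(empirical) == 0))
    abort("both graphs must have at least one edge.")
  a <- energy_stats(simulated)
  b <- if (is.null(empirical_stats)) energy_stats(empirical) else empirical_stats
  ks <- vapply(c("degree", "clustering", "betweenness", "edge_length"),
               function(m) ks_statistic(a[[m]], b[[m]]), numeric(1))
  tibble::tibble(ks_degree = ks[["degree"]], ks_clustering = ks[["clustering"]],
                 ks_betweenness = ks[["betweenness"]],
                 ks_edge_length = ks[["edge_length"]], energy = max(ks))
}

fingerprint_metrics <- c("degree", "clustering", "betweenness", "edge_length",
                         "local_efficiency", "eigenvector_centrality")

#' Topological fingerprint of a network
#'
#' The 6 x 6 Pearson correlation matrix, across nodes, of degree,
#' clustering, betweenness-centrality, edge length, local efficiency and
#' eigenvector centrality.  A metric with zero variance across nodes has
#' its row and column set to 0 (diagonal kept at 1) so fingerprints stay
#' comparable across graphs.
#'
#' @param graph a [spatial_graph()] with at least 3 nodes.
#' @return a `fingerprint` (6 x 6 matrix).
#' @export
fingerprint <- function(graph) {
  if (n_nodes(graph) < 3) abort("need at least 3 nodes.")
  m <- as.matrix(nodal_metrics(graph)[, fingerprint_metrics])
  flat <- apply(m, 2, sd) == 0
  fp <- suppressWarnings(cor(m))
  if (any(flat)) {
    warn(sprintf("zero-variance metric(s) %s: fingerprint row/column set to 0.",
                 paste(fingerprint_metrics[flat], collapse = ", ")))
    fp[flat, ] <- 0
    fp[, flat] <- 0
  }
  fp[is.na(fp)] <- 0
  diag(fp) <- 1
  structure(fp, class = c("fingerprint", "matrix"))
}

#' Dissimilarity between two topological fingerprints
#'
#' Euclidean (Frobenius) norm of the entrywise difference.
#'
#' @param a,b `fingerprint` matrices with the same metric order.
#' @return non-negative value; 0 iff the fingerprints are equal.
#' @export
tf_dissimilarity <- function(a, b) {
  if (!all(dim(a) == dim(b))) abort("fingerprints must have the same shape.")
  sqrt(sum((unclass(a) - unclass(b))^2))
}

#' Spatial similarity of two networks
#'
#' Node-matched Pearson correlation of the two degree sequences; tests
#' whether connections occupy the same anatomical locations.
#'
#' @param simulated,empirical [spatial_graph()]s on the same node set.
#' @return Pearson r, or `NA` (with a warning) when a degree sequence has
#'   zero variance.
#' @export
spatial_similarity <- function(simulated, empirical) {
  a <- rowSums(simulated$adjacency)
  b <- rowSums(empirical$adjacency)
  if (length(a) != length(b)) abort("graphs must share the node set.")
  if (sd(a) == 0 || sd(b) == 0) {
    warn("zero degree variance: spatial similarity undefined.")
    return(NA_real_)
  }
  cor(a, b)
}

#' Grid search over wiring parameters
#'
#' Runs one simulation (or `n_repeats`) per `(eta, gamma)` grid point and
#' scores each against the empirical target with the KS energy.  The best
#' point minimises energy (ties broken by smaller KS sum, then
#' lexicographically by parameters); the reported window spans the
#' lowest-energy `top_fraction` of the grid.
#'
#' @param seed seed [spatial_graph()] shared by all simulations.
#' @param target empirical target [spatial_graph()] (sets the edge count).
#' @param rule one of [wiring_rules()].
#' @param grid tibble `eta`, `gamma` (see [build_grid()]).
#' @param rng_seed integer seed; per-point streams are derived from the
#'   parameter values so duplicated points replay identically.
#' @param n_repeats simulations per grid point (default 1).  With repeats,
#'   the best point minimises the per-point *mean* energy.
#' @param top_fraction fraction of lowest-energy records bounding the
#'   reported parameter window (default 0.10).
#' @return a `gnm_fit` with `records` (one row per simulation),
#'   `best_params`, `best` (best per-point summary row), `top_window`,
#'   `rule`.
#' @export
grid_search <- function(seed, target, rule, grid, rng_seed,
                        n_repeats = 1, top_fraction = 0.10) {
  if (nrow(grid) == 0) abort("`grid` must be non-empty.")
  target_edges <- edge_count(target)
  d <- distance_matrix(target)
  emp <- energy_stats(target, d)
  records <- purrr::pmap_dfr(
    tidyr::expand_grid(grid, rep = seq_len(n_repeats)),
    function(eta, gamma, rep) {
      tr <- simulate_gnm(seed, target_edges, rule,
                         gnm_params(eta, gamma),
                         rng_seed = param_seed(rng_seed, eta, gamma, rep))
      sim_stats <- energy_stats(tr$final, d)
      ks <- vapply(names(sim_stats),
                   function(m) ks_statistic(sim_stats[[m]], emp[[m]]),
                   numeric(1))
      tibble::tibble(eta = eta, gamma = gamma, rep = rep,
                     ks_degree = ks[["degree"]],
                     ks_clustering = ks[["clustering"]],
                     ks_betweenness = ks[["betweenness"]],
                     ks_edge_length = ks[["edge_length"]], energy = max(ks))
    })
  points <- dplyr::summarise(
    dplyr::group_by(records, .data$eta, .data$gamma),
    dplyr::across(dplyr::starts_with("ks_"), mean), energy = mean(.data$energy),
    .groups = "drop")
  ord <- order(points$energy,
               points$ks_degree + points$ks_clustering +
                 points$ks_betweenness + points$ks_edge_length,
               points$eta, points$gamma)
  best <- points[ord[1], ]
  top_n <- max(1L, ceiling(top_fraction * nrow(points)))
  top <- points[ord[seq_len(top_n)], ]
  structure(list(records = records,
                 best = best,
                 best_params = gnm_params(best$eta, best$gamma),
                 top_window = list(eta = range(top$eta),
                                   gamma = range(top$gamma),
                                   fraction = top_fraction),
                 rule = rule, rng_seed = rng_seed),
            class = "gnm_fit")
}

#' @export
print.gnm_fit <- function(x, ...) {
  cat(sprintf("<gnm_fit> rule %s: best energy %.4f at eta %.3f, gamma %.3f (%d records)\n",
              x$rule, x$best$energy, x$best$eta, x$best$gamma, nrow(x$records)))
  invisible(x)
}

#' @export
tidy.gnm_fit <- function(x, ...) x$records

#' @export
glance.gnm_fit <- function(x, ...) {
  tibble::tibble(rule = x$rule, eta = x$best$eta, gamma = x$best$gamma,
                 energy = x$best$energy,
                 eta_window_low = x$top_window$eta[1],
                 eta_window_high = x$top_window$eta[2],
                 gamma_window_low = x$top_window$gamma[1],
                 gamma_window_high = x$top_window$gamma[2],
                 n_records = nrow(x$records))
}

#' Re-evaluate a parameter point with repeated simulations
#'
#' Computes the three model-selection criteria (mean energy, mean
#' topological-fingerprint dissimilarity, mean spatial degree correlation)
#' over `n_repeats` fresh simulations at a single parameter point.
#'
#' @param seed,target [spatial_graph()]s as in [grid_search()].
#' @param rule one of [wiring_rules()].
#' @param params a [gnm_params()].
#' @param n_repeats number of repeated simulations.
#' @param rng_seed integer seed.
#' @return one-row tibble `rule`, `eta`, `gamma`, `energy`,
#'   `tf_dissimilarity`, `spatial_r`.
#' @export
evaluate_params <- function(seed, target, rule, params, n_repeats, rng_seed) {
  emp <- energy_stats(target)
  fp_emp <- fingerprint(target)
  target_edges <- edge_count(target)
  runs <- purrr::map_dfr(seq_len(n_repeats), function(r) {
    tr <- simulate_gnm(seed, target_edges, rule, params,
                       rng_seed = param_seed(rng_seed, params$eta,
                                             params$gamma, r))
    tibble::tibble(
      energy = energy(tr$final, target, empirical_stats = emp)$energy,
      tf = tf_dissimilarity(fingerprint(tr$final), fp_emp),
      sp = spatial_similarity(tr$final, target))
  })
  tibble::tibble(rule = rule, eta = params$eta, gamma = params$gamma,
                 energy = mean(runs$energy), tf_dissimilarity = mean(runs$tf),
                 spatial_r = mean(runs$sp, na.rm = TRUE))
}

#' Cumulative-rank model selection
#'
#' Ranks each wiring rule on the three criteria (ascending for energy and
#' fingerprint dissimilarity, descending for spatial correlation) and
#' selects the smallest rank sum; ties are broken by the energy rank.
#'
#' @param criteria tibble with columns `rule`, `energy`,
#'   `tf_dissimilarity`, `spatial_r`, one row per rule.
#' @return the input ordered by cumulative rank, with `rank_energy`,
#'   `rank_tf`, `rank_spatial`, `rank_sum` and `selected` columns.
#' @export
rank_models <- function(criteria) {
  needed <- c("rule", "energy", "tf_dissimilarity", "spatial_r")
  if (!all(needed %in% names(criteria)))
    abort(sprintf("`criteria` must contain columns %s.",
                  paste(needed, collapse = ", ")))
  if (anyNA(criteria[, needed]))
    abort("missing criterion value(s) in `criteria`.")
  out <- dplyr::mutate(criteria,
                       rank_energy = rank(.data$energy),
                       rank_tf = rank(.data$tf_dissimilarity),
                       rank_spatial = rank(-.data$spatial_r),
                       rank_sum = .data$rank_energy + .data$rank_tf +
                         .data$rank_spatial)
  out <- dplyr::arrange(out, .data$rank_sum, .data$rank_energy)
  dplyr::mutate(out, selected = dplyr::row_number() == 1L)
}

#' Degree-preserving Maslov-Sneppen rewiring
#'
#' Randomises topology while retaining the exact degree sequence: pairs of
#' edges `(a,b)`, `(c,d)` are repeatedly swapped to `(a,d)`, `(c,b)`,
#' rejecting self-loops and multi-edges, until one accepted swap per edge
#' (budget = edge count) has been performed.
#'
#' @param graph a [spatial_graph()] with at least 2 independent edges.
#' @param rng_seed integer seed.
#' @return a rewired [spatial_graph()] with the input degree sequence.
#' @export
maslov_sneppen <- function(graph, rng_seed) {
  m <- edge_count(graph)
  if (m < 2) {
    warn("fewer than 2 edges: returning the input graph unchanged.")
    return(graph)
  }
  adj <- graph$adjacency
  edges <- which(upper.tri(adj) & adj == 1L, arr.ind = TRUE)
  withr::with_seed(rng_seed, {
    accepted <- 0L
    attempts <- 0L
    max_attempts <- 200L * m
    while (accepted < m && attempts < max_attempts) {
      attempts <- attempts + 1L
      pick <- sample.int(m, 2)
      a <- edges[pick[1], 1]; b <- edges[pick[1], 2]
      c_ <- edges[pick[2], 1]; d <- edges[pick[2], 2]
      if (runif(1) < 0.5) { tmp <- c_; c_ <- d; d <- tmp }
      # propose (a,d) and (c_,b)
      if (a == d || c_ == b) next
      if (adj[a, d] == 1L || adj[c_, b] == 1L) next
      adj[a, b] <- adj[b, a] <- 0L
      adj[c_, d] <- adj[d, c_] <- 0L
      adj[a, d] <- adj[d, a] <- 1L
      adj[c_, b] <- adj[b, c_] <- 1L
      edges[pick[1], ] <- c(min(a, d), max(a, d))
      edges[pick[2], ] <- c(min(c_, b), max(c_, b))
      accepted <- accepted + 1L
    }
    if (accepted < m)
      warn(sprintf("rewiring stalled after %d attempts (%d/%d swaps accepted).",
                   attempts, accepted, m))
  })
  rewrap_graph(adj, graph)
}
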