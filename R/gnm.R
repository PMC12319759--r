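#' Wiring-equation parameters
#'
#' The generative model connects node pairs with probability proportional
#' to `D^eta * (K + epsilon)^gamma`, where `D` is the Euclidean distance
#' and `K` the topological value under the chosen rule.  `epsilon` is a
#' small positive constant keeping the probability defined when `K = 0`;
#' it is added at every iteration because disconnected pairs can return to
#' zero value at any step.
#'
#' @param eta distance-penalty exponent (finite; negative values penalise
#'   long connections).
#' @param gamma topological-value exponent (finite).
#' @param epsilon small additive constant (> 0), default `1e-6`.
#' @return a `gnm_params` list.
#' @export
gnm_params <- function(eta, gamma, epsilon = 1e-6) {
  if (!is.finite(eta) || !is.finite(gamma))
    abort("`eta` and `gamma` must be finite.")
  if (!is.finite(epsilon) || epsilon <= 0)
    abort("`epsilon` must be a small positive constant.")
  structure(list(eta = eta, gamma = gamma, epsilon = epsilon),
            class = "gnm_params")
}

#' @export
print.gnm_params <- function(x, ...) {
  cat(sprintf("<gnm_params> eta = %.4g, gamma = %.4g, epsilon = %g\n",
              x$eta, x$gamma, x$epsilon))
  invisible(x)
}

#' The five wiring rules
#'
#' `spatial` (value identically 1, geometry only), the two homophily rules
#' `matching` (normalised neighbourhood overlap, in `[0, 1]`) and
#' `neighbours` (shared-neighbour count), and the `clustering_average` and
#' `degree_average` rules (mean of the two nodal values).
#'
#' @return character vector of rule names.
#' @export
wiring_rules <- function() {
  c("spatial", "matching", "neighbours", "clustering_average", "degree_average")
}

rule_code <- function(rule) {
  i <- match(rule, wiring_rules())
  if (is.na(i)) abort(sprintf("unknown wiring rule '%s'.", rule))
  i - 1L
}

#' Topological value matrix of a graph under a wiring rule
#'
#' @param graph a [spatial_graph()].
#' @param rule one of [wiring_rules()].
#' @return symmetric non-negative `n x n` matrix `K` (diagonal 0; for the
#'   `spatial` rule all off-diagonal entries are 1).
#' @export
topological_value <- function(graph, rule) {
  topological_value_cpp(graph$adjacency, rule_code(rule))
}

#' Wiring probabilities over unconnected node pairs
#'
#' Evaluates `D^eta * (K + epsilon)^gamma` for every unconnected pair
#' `i < j` of the current graph and normalises to a probability vector.
#'
#' @param K topological value matrix (see [topological_value()]).
#' @param D distance matrix, strictly positive off the diagonal.
#' @param current a [spatial_graph()] giving the connected pairs to exclude.
#' @param params a [gnm_params()].
#' @return tibble `from`, `to`, `probability` in lexicographic pair order,
#'   summing to 1.
#' @export
wiring_probabilities <- function(K, D, current, params) {
  stopifnot(inherits(params, "gnm_params"))
  n <- n_nodes(current)
  offdiag <- D[upper.tri(D)]
  if (any(offdiag <= 0)) abort("`D` must be strictly positive off-diagonal.")
  ut <- upper.tri(D)
  cand <- ut & current$adjacency == 0L
  if (!any(cand)) abort("graph saturated: no unconnected pairs.")
  w <- D[cand]^params$eta * (K[cand] + params$epsilon)^params$gamma
  idx <- which(cand, arr.ind = TRUE)
  ord <- order(idx[, 1], idx[, 2])
  tibble::tibble(from = idx[ord, 1], to = idx[ord, 2],
                 probability = (w / sum(w))[ord])
}

#' Grow a network with the generative wiring model
#'
#' Starting from `seed`, adds one edge per iteration, sampled from the
#' wiring probabilities under `rule` and `params`, until `target_edges`
#' edges exist.  The topological value matrix is updated after every
#' addition.  Runs are bit-reproducible for a fixed `rng_seed`.
#'
#' @param seed a [spatial_graph()] starting network.
#' @param target_edges final edge count (`seed` edges <= `target_edges`
#'   <= `n(n-1)/2`).
#' @param rule one of [wiring_rules()].
#' @param params a [gnm_params()].
#' @param rng_seed integer seed.
#' @param record if `TRUE`, per-iteration parameterised nodal terms and
#'   per-iteration nodal probability mass are stored on the trace (needed
#'   by [parameterised_nodal_terms()]; costs roughly double per iteration).
#' @return a `gnm_trace` with elements `seed`, `added_edges` (k x 2),
#'   `final` ([spatial_graph()]), `params`, `rule`, `rng_seed`,
#'   `prob_node_mean`, and, when recorded, `nodal_cost`, `nodal_value`,
#'   `value_iter`, `prob_iter`.
#' @export
simulate_gnm <- function(seed, target_edges, rule, params, rng_seed,
                         record = FALSE) {
  stopifnot(inherits(seed, "spatial_graph"), inherits(params, "gnm_params"))
  n <- n_nodes(seed)
  n_pairs <- n * (n - 1) / 2
  e0 <- edge_count(seed)
  if (target_edges < e0 || target_edges > n_pairs)
    abort(sprintf(
      "infeasible target: %d edges requested, seed has %d, maximum is %d.",
      target_edges, e0, n_pairs))
  d <- distance_matrix(seed)
  if (any(d[upper.tri(d)] <= 0))
    abort("coincident node coordinates: distances must be strictly positive.")
  n_add <- target_edges - e0
  res <- withr::with_seed(rng_seed,
    gnm_simulate_cpp(seed$adjacency, d, params$eta, params$gamma,
                     params$epsilon, rule_code(rule), n_add, record))
  trace <- list(seed = seed,
                added_edges = res$edges,
                final = rewrap_graph(res$final, seed),
                params = params, rule = rule, rng_seed = rng_seed,
                prob_node_mean = as.numeric(res$prob_node_mean))
  if (record) {
    dp <- d^params$eta
    diag(dp) <- 0
    trace$nodal_cost <- unname(rowSums(dp))
    trace$nodal_value <- as.numeric(res$nodal_value)
    trace$value_iter <- res$value_iter
    trace$prob_iter <- res$prob_iter
  }
  structure(trace, class = "gnm_trace")
}

#' @export
print.gnm_trace <- function(x, ...) {
  cat(sprintf("<gnm_trace> rule %s, eta %.3f, gamma %.3f: %d seed + %d added edges\n",
              x$rule, x$params$eta, x$params$gamma,
              edge_count(x$seed), nrow(x$added_edges)))
  invisible(x)
}

#' Parameterised nodal wiring cost and value of a recorded trace
#'
#' For node `i`, cost is `sum_j D_ij^eta` (fixed geometry) and value is the
#' mean over iterations of `sum_j (K_ij + epsilon)^gamma`, the topological
#' term as it evolved during the simulation.  These are the nodal maps
#' decoded against regional gene expression.
#'
#' @param trace a `gnm_trace` from [simulate_gnm()] with `record = TRUE`.
#' @return tibble `node`, `cost`, `value`.
#' @export
parameterised_nodal_terms <- function(trace) {
  stopifnot(inherits(trace, "gnm_trace"))
  if (is.null(trace$nodal_value))
    abort("trace was not recorded; rerun simulate_gnm() with record = TRUE.")
  tibble::tibble(node = seq_len(n_nodes(trace$seed)),
                 cost = trace$nodal_cost, value = trace$nodal_value)
}

#' Equally spaced parameter grid
#'
#' `floor(sqrt(budget))` points per axis including the endpoints, crossed
#' into their Cartesian product: a budget of 100,000 over `[-7, 7]^2`
#' yields 316 points per axis and 99,856 unique pairs.
#'
#' @param budget total simulation budget (>= 1).
#' @param eta_range,gamma_range numeric length-2 intervals.
#' @return tibble `eta`, `gamma` with `floor(sqrt(budget))^2` rows.
#' @export
build_grid <- function(budget, eta_range = c(-7, 7), gamma_range = c(-7, 7)) {
  if (budget < 1) abort("`budget` must be at least 1.")
  if (diff(range(eta_range)) == 0 || diff(range(gamma_range)) == 0)
    abort("parameter ranges must be non-degenerate.")
  m <- floor(sqrt(budget))
  etas <- seq(eta_range[1], eta_range[2], length.out = max(m, 1))
  gammas <- seq(gamma_range[1], gamma_range[2], length.out = max(m, 1))
  grid <- tidyr::expand_grid(eta = etas, gamma = gammas)
  message(sprintf("grid: %d x %d = %d unique parameter pairs",
                  length(etas), length(gammas), nrow(grid)))
  grid
}

# Deterministic per-parameter-point sub-seed: a function of the base seed
# and the parameter values (not the grid position), so duplicated grid
# points replay identical RNG streams.
param_seed <- function(rng_seed, eta, gamma, rep = 1L) {
  key <- sprintf("%.10e|%.10e|%d", eta, gamma, rep)
  h <- 0
  for (v in utf8ToInt(key)) h <- (h * 131 + v) %% 2147483629
  as.integer((h + rng_seed) %% 2147483629 + 1)
}
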