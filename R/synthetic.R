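#' Sample node coordinates in an ellipsoidal shell
#'
#' Stands in for parcellation centroids.  Points are drawn uniformly inside
#' an anisotropic ellipsoidal shell whose elongated anterior-posterior axis
#' mimics a cerebral hemisphere; this geometry yields the right-skewed
#' inter-node distance distribution seen in empirical centroid tables.
#'
#' @param n_nodes number of nodes (>= 3).
#' @param rng_seed integer seed; the output is a pure function of the seed.
#' @param semi_axes ellipsoid semi-axes in mm.
#' @param inner_fraction inner radius of the shell as a fraction of the
#'   ellipsoid surface (0 gives a filled ellipsoid).
#'
#' @return tibble with columns `node`, `x`, `y`, `z` (mm).
#' @examples
#' coords <- generate_coordinates(100, rng_seed = 7)
#' @export
generate_coordinates <- function(n_nodes, rng_seed,
                                 semi_axes = c(110, 55, 40),
                                 inner_fraction = 0.3) {
  if (n_nodes < 3) abort("`n_nodes` must be at least 3.")
  stopifnot(length(semi_axes) == 3, all(semi_axes > 0),
            inner_fraction >= 0, inner_fraction < 1)
  withr::with_seed(rng_seed, {
    pts <- matrix(NA_real_, n_nodes, 3)
    k <- 0L
    while (k < n_nodes) {
      p <- runif(3, -1, 1)
      q <- sum(p^2)
      if (q <= 1 && q >= inner_fraction^2) {
        k <- k + 1L
        pts[k, ] <- p * semi_axes
      }
    }
    tibble::tibble(node = seq_len(n_nodes),
                   x = pts[, 1], y = pts[, 2], z = pts[, 3])
  })
}

#' Cohort specification for the synthetic connectome generator
#'
#' Defaults are the fitted participant-level parameter distributions of the
#' modelled cohort: eta ~ N(-3.007, 0.336), gamma ~ N(0.215, 0.027), 100
#' nodes at 6.5% density, and a standardized polygenic-score slope of .054
#' on the wiring distance penalty.
#'
#' @param n_participants cohort size.
#' @param n_nodes nodes per connectome (>= 3).
#' @param target_density edge density of every generated connectome, in (0,1).
#' @param eta_mean,eta_sd distance-penalty exponent distribution.
#' @param gamma_mean,gamma_sd topological-value exponent distribution
#'   (`eta_sd`, `gamma_sd` >= 0).
#' @param pgs_beta planted standardized slope of polygenic score on eta.
#' @param rng_seed integer seed.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_participants, n_nodes = 100, target_density = 0.065,
                        eta_mean = -3.007, eta_sd = 0.336,
                        gamma_mean = 0.215, gamma_sd = 0.027,
                        pgs_beta = 0.054, rng_seed = 1L) {
  if (n_nodes < 3) abort("`n_nodes` must be at least 3.")
  if (target_density <= 0 || target_density >= 1)
    abort("`target_density` must lie in (0, 1).")
  if (eta_sd < 0 || gamma_sd < 0)
    abort("`eta_sd` and `gamma_sd` must be non-negative.")
  structure(list(n_participants = as.integer(n_participants),
                 n_nodes = as.integer(n_nodes),
                 target_density = target_density,
                 eta_mean = eta_mean, eta_sd = eta_sd,
                 gamma_mean = gamma_mean, gamma_sd = gamma_sd,
                 pgs_beta = pgs_beta, rng_seed = as.integer(rng_seed)),
            class = "cohort_spec")
}

#' Build a common seed network for a synthetic cohort
#'
#' Mirrors the empirical seed construction: a stack of distance-dependent
#' random graphs is generated at roughly the raw (pre-threshold) density,
#' and the edges present in at least `prevalence` of the stack become the
#' seed.  Short connections have near-unit probability, so the seed is a
#' sparse spatially compact core shared by every simulation.
#'
#' @param coordinates coordinate table (see [generate_coordinates()]).
#' @param rng_seed integer seed.
#' @param n_stack number of random graphs in the stack.
#' @param stack_density target mean density of the stack.
#' @param length_scale exponential decay scale of the edge probability (mm).
#' @param prevalence prevalence cut for seed membership (default .95).
#' @return a [spatial_graph()] seed network.
#' @export
make_cohort_seed <- function(coordinates, rng_seed, n_stack = 20,
                             stack_density = 0.13, length_scale = 18,
                             prevalence = 0.95) {
  coords <- as_coord_matrix(coordinates)
  d <- as.matrix(dist(coords))
  n <- nrow(coords)
  decay <- exp(-d / length_scale)
  diag(decay) <- 0
  # fixed-point scaling so the capped probabilities hit the target density
  p <- decay
  for (i in 1:25) {
    m <- mean(p[upper.tri(p)])
    if (m <= 0) abort("degenerate geometry: all edge probabilities zero")
    p <- pmin(p * stack_density / m, 1) # matrix first: pmin keeps its dims
  }
  withr::with_seed(rng_seed, {
    graphs <- lapply(seq_len(n_stack), function(s) {
      u <- matrix(0, n, n)
      u[upper.tri(u)] <- runif(n * (n - 1) / 2)
      a <- (u < p & upper.tri(u)) * 1L
      spatial_graph(a + t(a), coords)
    })
    seed_network(graphs, prevalence = prevalence)
  })
}

#' Generate a cohort of synthetic connectomes with known wiring parameters
#'
#' Each participant's connectome grows from the shared `seed_graph` under
#' the `neighbours` homophily rule, with participant-specific exponents
#' drawn from the cohort distributions in `spec`, until it reaches
#' `round(target_density * n(n-1)/2)` edges.
#'
#' @param spec a [cohort_spec()].
#' @param seed_graph a [spatial_graph()] strictly sparser than the target
#'   density; its edges appear in every participant graph.
#' @param rule wiring rule used to grow the cohort (default `"neighbours"`).
#' @return list with `graphs` (list of [spatial_graph()]) and `truth`
#'   (tibble `id`, `eta`, `gamma`).
#' @export
generate_cohort <- function(spec, seed_graph, rule = "neighbours") {
  stopifnot(inherits(spec, "cohort_spec"), inherits(seed_graph, "spatial_graph"))
  n <- spec$n_nodes
  if (n_nodes(seed_graph) != n)
    abort("`seed_graph` node count does not match `spec$n_nodes`.")
  n_pairs <- n * (n - 1) / 2
  target_edges <- round(spec$target_density * n_pairs)
  if (edge_count(seed_graph) >= target_edges)
    abort("infeasible target: seed graph is at least as dense as the target.")
  draws <- withr::with_seed(spec$rng_seed, {
    list(eta = rnorm(spec$n_participants, spec$eta_mean, spec$eta_sd),
         gamma = rnorm(spec$n_participants, spec$gamma_mean, spec$gamma_sd),
         sim_seeds = sample.int(.Machine$integer.max - 1L, spec$n_participants))
  })
  graphs <- purrr::pmap(
    list(draws$eta, draws$gamma, draws$sim_seeds),
    function(eta, gamma, s) {
      simulate_gnm(seed_graph, target_edges, rule = rule,
                   params = gnm_params(eta, gamma),
                   rng_seed = s, record = FALSE)$final
    })
  list(graphs = graphs,
       truth = tibble::tibble(id = seq_len(spec$n_participants),
                              eta = draws$eta, gamma = draws$gamma))
}

#' Generate polygenic scores with a planted association to the wiring penalty
#'
#' Scores are built as `beta * z(eta) + sqrt(1 - beta^2) * noise` and then
#' standardized, so the expected standardized regression slope of score on
#' `z(eta)` equals `pgs_beta`.
#'
#' @param true_etas numeric vector of per-participant wiring penalties
#'   (length >= 3).
#' @param pgs_beta planted standardized slope, `|pgs_beta| <= 1`.
#' @param rng_seed integer seed.
#' @return standardized numeric score vector (mean 0, SD 1).
#' @export
generate_pgs <- function(true_etas, pgs_beta, rng_seed) {
  if (length(true_etas) < 3) abort("need at least 3 participants.")
  if (!is.finite(pgs_beta) || abs(pgs_beta) > 1)
    abort("`pgs_beta` must be finite with |pgs_beta| <= 1.")
  s <- sd(true_etas)
  if (s == 0) {
    if (pgs_beta != 0)
      warn("degenerate signal: `true_etas` has zero variance; scores carry no eta signal.")
    z <- rep(0, length(true_etas))
  } else {
    z <- (true_etas - mean(true_etas)) / s
  }
  withr::with_seed(rng_seed, {
    raw <- pgs_beta * z + sqrt(max(0, 1 - pgs_beta^2)) * rnorm(length(z))
    as.numeric(scale(raw))
  })
}

#' Expression-matrix specification
#'
#' Emulates a left-hemisphere regional microarray block (e.g. 50 regions by
#' many genes): non-signal genes are smooth Gaussian random fields over the
#' region coordinates with squared-exponential covariance; signal genes mix
#' a supplied nodal target map with spatial noise at a stated correlation.
#'
#' @param n_regions number of regions (rows).
#' @param n_genes number of genes (columns).
#' @param spatial_length_scale Gaussian-field length scale (mm).
#' @param n_signal_genes number of planted signal genes (<= `n_genes`).
#' @param signal_strength expected |correlation| of signal genes with the
#'   target map, in `[0, 1]`.
#' @param rng_seed integer seed.
#' @return an `expression_spec` list.
#' @export
expression_spec <- function(n_regions = 50, n_genes = 500,
                            spatial_length_scale = 30,
                            n_signal_genes = 25, signal_strength = 0.6,
                            rng_seed = 1L) {
  if (spatial_length_scale <= 0) abort("`spatial_length_scale` must be positive.")
  if (n_signal_genes > n_genes) abort("`n_signal_genes` cannot exceed `n_genes`.")
  if (signal_strength < 0 || signal_strength > 1)
    abort("`signal_strength` must lie in [0, 1].")
  structure(list(n_regions = as.integer(n_regions),
                 n_genes = as.integer(n_genes),
                 spatial_length_scale = spatial_length_scale,
                 n_signal_genes = as.integer(n_signal_genes),
                 signal_strength = signal_strength,
                 rng_seed = as.integer(rng_seed)),
            class = "expression_spec")
}

#' Generate a spatially autocorrelated region-by-gene expression matrix
#'
#' @param spec an [expression_spec()].
#' @param coordinates coordinate table with `spec$n_regions` rows.
#' @param target_map nodal vector (length `n_regions`) that signal genes
#'   track at the planted correlation.
#' @return numeric `n_regions x n_genes` matrix with gene-id column names;
#'   the planted genes are recorded in `attr(, "signal_genes")`.
#' @export
generate_expression <- function(spec, coordinates, target_map) {
  stopifnot(inherits(spec, "expression_spec"))
  coords <- as_coord_matrix(coordinates)
  if (nrow(coords) != spec$n_regions)
    abort("`coordinates` must have `n_regions` rows.")
  if (length(target_map) != spec$n_regions)
    abort("`target_map` must have one value per region.")
  n <- spec$n_regions
  d <- as.matrix(dist(coords))
  covm <- exp(-d^2 / (2 * spec$spatial_length_scale^2))
  l <- t(chol(covm + diag(1e-8, n)))
  zmap <- as.numeric(scale(target_map))
  if (any(!is.finite(zmap))) abort("`target_map` has zero variance.")
  s <- spec$signal_strength
  withr::with_seed(spec$rng_seed, {
    expr <- vapply(seq_len(spec$n_genes), function(g) {
      field <- as.numeric(l %*% rnorm(n))
      if (g <= spec$n_signal_genes) {
        noise <- as.numeric(scale(field))
        s * zmap + sqrt(1 - s^2) * noise
      } else {
        field
      }
    }, numeric(n))
  })
  ids <- sprintf("gene%04d", seq_len(spec$n_genes))
  colnames(expr) <- ids
  attr(expr, "signal_genes") <- ids[seq_len(spec$n_signal_genes)]
  expr
}
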