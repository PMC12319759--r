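#' Remove parameter outliers from a cohort table
#'
#' Drops participants whose fitted `eta` or `gamma` lies more than
#' `k_sd` standard deviations from the mean, both computed on the input
#' table in a single pass.
#'
#' @param table cohort tibble with columns `eta` and `gamma`.
#' @param k_sd SD multiplier (> 0); the reference pipeline uses 2.
#' @return the filtered tibble.
#' @export
remove_outliers <- function(table, k_sd = 2) {
  if (k_sd <= 0) abort("`k_sd` must be positive.")
  stopifnot(all(c("eta", "gamma") %in% names(table)))
  keep_param <- function(x) {
    mu <- mean(x); s <- sd(x)
    if (s == 0) rep(TRUE, length(x)) else abs(x - mu) <= k_sd * s
  }
  out <- table[keep_param(table$eta) & keep_param(table$gamma), ]
  if (nrow(out) == 0) abort("outlier removal left an empty table.")
  out
}

# classic equal-variance two-sample t-test plus pooled-SD Cohen's d,
# reported as group_b minus group_a
contrast_groups <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / (n1 + n2 - 2)
  t <- (mean(b) - mean(a)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  tibble::tibble(t = t, df = df, p = 2 * pt(-abs(t), df),
                 cohens_d = (mean(b) - mean(a)) / sqrt(sp2))
}

#' Extreme polygenic-score group contrast of wiring parameters
#'
#' Selects the bottom and top `fraction` of the cohort by polygenic score
#' (group size `ceiling(fraction * n)`) and compares their fitted `eta`
#' and `gamma` with classic independent-sample t-tests
#' (`df = n1 + n2 - 2`) and pooled-SD Cohen's d.  Differences are
#' reported as bottom minus top, matching the reference contrast.
#'
#' @param table cohort tibble with columns `pgs`, `eta`, `gamma`.
#' @param fraction decile fraction in (0, 0.5).
#' @return tibble with one row per parameter: `parameter`, `mean_bottom`,
#'   `mean_top`, `t`, `df`, `p`, `cohens_d`.
#' @export
extreme_group_contrast <- function(table, fraction = 0.10) {
  if (fraction >= 0.5 || fraction <= 0) abort("`fraction` must lie in (0, .5).")
  stopifnot(all(c("pgs", "eta", "gamma") %in% names(table)))
  n <- nrow(table)
  g <- ceiling(fraction * n)
  if (g < 2) abort("groups need at least 2 members.")
  ord <- order(table$pgs)
  bottom <- table[ord[seq_len(g)], ]
  top <- table[ord[seq(n - g + 1, n)], ]
  purrr::map_dfr(c("eta", "gamma"), function(par) {
    ct <- contrast_groups(top[[par]], bottom[[par]]) # bottom minus top
    dplyr::bind_cols(tibble::tibble(parameter = par,
                                    mean_bottom = mean(bottom[[par]]),
                                    mean_top = mean(top[[par]])), ct)
  })
}

#' Continuous polygenic-score association with wiring parameters
#'
#' Linear model of each standardized parameter on the standardized
#' polygenic score, controlling for mean framewise displacement, sex and
#' age; the fully standardized slope on the score is reported with its
#' p-value and a Bonferroni correction over the two parameters tested
#' (`p_bonf = min(1, 2p)`).
#'
#' @param table cohort tibble with columns `eta`, `gamma`, `pgs`,
#'   `mean_fd`, `sex`, `age`.
#' @return tibble `parameter`, `beta`, `se`, `p`, `p_bonf`.
#' @export
pgs_glm <- function(table) {
  covars <- c("pgs", "mean_fd", "sex", "age")
  missing <- setdiff(c("eta", "gamma", covars), names(table))
  if (length(missing) > 0)
    abort(sprintf("cohort table lacks column(s): %s.",
                  paste(missing, collapse = ", ")))
  df <- data.frame(z_pgs = as.numeric(scale(table$pgs)),
                   mean_fd = table$mean_fd,
                   sex = factor(table$sex),
                   age = table$age)
  purrr::map_dfr(c("eta", "gamma"), function(par) {
    df$y <- as.numeric(scale(table[[par]]))
    fit <- lm(y ~ z_pgs + mean_fd + sex + age, data = df)
    if (any(is.na(stats::coef(fit)))) {
      bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
      abort(sprintf("rank-deficient design: collinear term(s) %s.",
                    paste(bad, collapse = ", ")))
    }
    sm <- summary(fit)$coefficients["z_pgs", ]
    tibble::tibble(parameter = par, beta = sm[["Estimate"]],
                   se = sm[["Std. Error"]], p = sm[["Pr(>|t|)"]],
                   p_bonf = min(1, 2 * sm[["Pr(>|t|)"]]))
  })
}

# one simulated group of the stochasticity experiment
simulate_group <- function(params, seed, target_edges, n_sims, seeds,
                           rule, max_pairs) {
  n <- n_nodes(seed)
  prob_node <- matrix(NA_real_, n_sims, n)
  edge_sets <- vector("list", n_sims)
  fps <- vector("list", n_sims)
  eff <- numeric(n_sims)
  for (s in seq_len(n_sims)) {
    tr <- simulate_gnm(seed, target_edges, rule, params, rng_seed = seeds[s])
    prob_node[s, ] <- tr$prob_node_mean
    edge_sets[[s]] <- edge_index_set(tr$final)
    fps[[s]] <- fingerprint(tr$final)
    eff[s] <- global_efficiency(tr$final)
  }
  # pairwise dissimilarities over a deterministic subsample of sim pairs
  all_pairs <- utils::combn(n_sims, 2)
  if (ncol(all_pairs) > max_pairs)
    all_pairs <- all_pairs[, seq(1, ncol(all_pairs),
                                 length.out = max_pairs), drop = FALSE]
  jac <- numeric(ncol(all_pairs)); tfd <- numeric(ncol(all_pairs))
  for (k in seq_len(ncol(all_pairs))) {
    i <- all_pairs[1, k]; j <- all_pairs[2, k]
    inter <- length(intersect(edge_sets[[i]], edge_sets[[j]]))
    uni <- length(edge_sets[[i]]) + length(edge_sets[[j]]) - inter
    jac[k] <- 1 - inter / uni
    tfd[k] <- tf_dissimilarity(fps[[i]], fps[[j]])
  }
  list(prob_cv = coefficient_of_variation(prob_node)$cv,
       embedding_dissimilarity = jac,
       topological_dissimilarity = tfd,
       global_efficiency = eff)
}

#' Stochasticity consequences of softening the wiring penalty
#'
#' Simulates `n_sims` networks per parameter set and contrasts four
#' consequences of the softer penalty: per-node coefficient of variation
#' of wiring-probability mass across simulations, embedding dissimilarity
#' (mean pairwise Jaccard distance between edge sets), topological
#' dissimilarity (pairwise fingerprint distance), and global efficiency.
#' Contrasts (`high` minus `low`) use classic t-tests and pooled Cohen's d.
#'
#' The wiring-probability CV convention: for each simulation and node, the
#' node's summed candidate probability is averaged over iterations; the CV
#' is then taken across simulations per node (so that distribution has one
#' value per node, not per simulation).
#'
#' @param params_low,params_high [gnm_params()] for the two groups (e.g.
#'   the bottom- and top-decile group means).
#' @param seed shared seed [spatial_graph()].
#' @param target_edges edge count of every simulation.
#' @param n_sims simulations per group (>= 2).
#' @param rng_seed integer seed.
#' @param rule wiring rule (default `"neighbours"`).
#' @param max_pairs maximum simulation pairs entering the pairwise
#'   dissimilarity distributions (default 1000).
#' @return a `stochasticity_report`: list with `low`, `high` (distribution
#'   lists) and `contrasts` (tibble `measure`, `t`, `df`, `p`, `cohens_d`).
#' @export
stochasticity_experiment <- function(params_low, params_high, seed,
                                     target_edges, n_sims, rng_seed,
                                     rule = "neighbours", max_pairs = 1000) {
  if (n_sims < 2) abort("`n_sims` must be at least 2.")
  seeds <- withr::with_seed(rng_seed,
    matrix(sample.int(.Machine$integer.max - 1L, 2 * n_sims), ncol = 2))
  low <- simulate_group(params_low, seed, target_edges, n_sims, seeds[, 1],
                        rule, max_pairs)
  high <- simulate_group(params_high, seed, target_edges, n_sims, seeds[, 2],
                         rule, max_pairs)
  contrasts <- purrr::map_dfr(names(low), function(m) {
    a <- low[[m]][is.finite(low[[m]])]
    b <- high[[m]][is.finite(high[[m]])]
    dplyr::bind_cols(tibble::tibble(measure = m), contrast_groups(a, b))
  })
  structure(list(low = low, high = high, contrasts = contrasts,
                 params_low = params_low, params_high = params_high,
                 n_sims = n_sims),
            class = "stochasticity_report")
}

#' @export
print.stochasticity_report <- function(x, ...) {
  cat(sprintf("<stochasticity_report> %d simulations per group\n", x$n_sims))
  print(x$contrasts)
  invisible(x)
}

#' @export
tidy.stochasticity_report <- function(x, ...) x$contrasts

#' Scale wiring parameters towards randomness
#'
#' Multiplies both exponents by `fraction` (a fraction of 0 gives pure
#' random edge addition); values are rounded to 3 decimals for reporting.
#'
#' @param optimal a [gnm_params()].
#' @param fraction value in `[0, 1]`.
#' @return a [gnm_params()] with scaled, 3-decimal-rounded exponents.
#' @export
scale_params <- function(optimal, fraction) {
  stopifnot(inherits(optimal, "gnm_params"), fraction >= 0, fraction <= 1)
  gnm_params(round(fraction * optimal$eta, 3),
             round(fraction * optimal$gamma, 3),
             optimal$epsilon)
}

#' Parameter-randomisation sweep
#'
#' Runs the generative model at successively weakened fractions of the
#' optimal parameters, recording mean global efficiency and the mean
#' fingerprint dissimilarity to Maslov-Sneppen-rewired copies of the
#' empirical target.  As the parameters approach 0 the simulations become
#' random, efficiency rises, and the topology approaches the rewired null.
#'
#' @param optimal optimal [gnm_params()] (e.g. the group-level best fit).
#' @param fractions vector of fractions in `[0, 1]`.
#' @param seed shared seed [spatial_graph()].
#' @param target empirical target [spatial_graph()].
#' @param n_sims simulations per fraction.
#' @param rng_seed integer seed.
#' @param rule wiring rule (default `"neighbours"`).
#' @return tibble `fraction`, `eta`, `gamma`, `mean_global_efficiency`,
#'   `mean_tf_dissimilarity`.
#' @export
randomisation_sweep <- function(optimal, fractions, seed, target, n_sims,
                                rng_seed, rule = "neighbours") {
  if (any(fractions < 0 | fractions > 1)) abort("`fractions` must lie in [0, 1].")
  target_edges <- edge_count(target)
  seeds <- withr::with_seed(rng_seed,
    sample.int(.Machine$integer.max - 1L, n_sims * (length(fractions) + 1)))
  # pool of rewired targets, shared across fractions
  rewired_fps <- lapply(seq_len(n_sims), function(s)
    fingerprint(maslov_sneppen(target, rng_seed = seeds[s])))
  purrr::map_dfr(seq_along(fractions), function(fi) {
    pars <- scale_params(optimal, fractions[fi])
    eff <- numeric(n_sims); tfd <- numeric(n_sims)
    for (s in seq_len(n_sims)) {
      tr <- simulate_gnm(seed, target_edges, rule, pars,
                         rng_seed = seeds[fi * n_sims + s])
      eff[s] <- global_efficiency(tr$final)
      tfd[s] <- tf_dissimilarity(fingerprint(tr$final), rewired_fps[[s]])
    }
    tibble::tibble(fraction = fractions[fi], eta = pars$eta, gamma = pars$gamma,
                   mean_global_efficiency = mean(eff),
                   mean_tf_dissimilarity = mean(tfd))
  })
}
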