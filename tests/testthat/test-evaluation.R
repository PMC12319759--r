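test_that("the KS statistic equals direct CDF enumeration", {
  expect_equal(ks_statistic(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(ks_statistic(c(0, 0, 0), c(1, 1, 1)), 1)
  expect_equal(ks_statistic(1:4, 2:5), 0.25)  # hand-computed sup difference
  expect_error(ks_statistic(numeric(0), 1), "non-empty")
  for (s in 1:10) {
    a <- withr::with_seed(s, sample(1:8, 12, replace = TRUE))
    b <- withr::with_seed(s + 50, rnorm(7))
    expect_equal(ks_statistic(a, b), ks_oracle(a, b), tolerance = 1e-12)
  }
})

test_that("energy is zero on identical graphs and label permutations", {
  g <- random_graph(12, 20, rng_seed = 1)
  e <- energy(g, g)
  expect_equal(e$energy, 0)
  expect_equal(unlist(e[1, 1:4]), c(ks_degree = 0, ks_clustering = 0,
                                    ks_betweenness = 0, ks_edge_length = 0))

  # permuting node labels together with coordinates preserves all four
  # distributions, so energy stays 0 (distribution level, not node level)
  perm <- withr::with_seed(2, sample(12))
  gp <- spatial_graph(g$adjacency[perm, perm], g$coordinates[perm, ])
  expect_equal(energy(gp, g)$energy, 0)

  expect_error(energy(toy_graph(4, list()), g), "at least one edge")
})

test_that("energy equals the maximum of independently brute-forced components", {
  a <- random_graph(8, 12, rng_seed = 3)
  b <- random_graph(8, 12, rng_seed = 4)
  e <- energy(a, b)
  stats_of <- function(g) list(
    degree = rowSums(g$adjacency),
    clustering = nodal_metrics(g)$clustering,
    betweenness = betweenness_oracle(g$adjacency),
    edge_length = edge_table(g)$length)
  sa <- stats_of(a); sb <- stats_of(b)
  ks <- vapply(names(sa), function(m) ks_oracle(sa[[m]], sb[[m]]), numeric(1))
  expect_equal(e$ks_degree, ks[["degree"]])
  expect_equal(e$ks_betweenness, ks[["betweenness"]])
  expect_equal(e$energy, max(ks))
  expect_true(e$energy %in% unlist(e[1, 1:4]))
})

test_that("fingerprints are correlation matrices with flagged degenerate rows", {
  g <- random_graph(20, 40, rng_seed = 5)
  fp <- fingerprint(g)
  expect_equal(dim(fp), c(6, 6))
  expect_equal(unname(diag(unclass(fp))), rep(1, 6))
  expect_equal(unclass(fp), t(unclass(fp)))
  # recomputation oracle straight from the metric table
  m <- as.matrix(nodal_metrics(g)[, c("degree", "clustering", "betweenness",
                                      "edge_length", "local_efficiency",
                                      "eigenvector_centrality")])
  expect_equal(unclass(fp), unname(cor(m)), tolerance = 1e-12,
               ignore_attr = TRUE)

  # ring lattice: degree has zero variance -> row/column zeroed with warning
  ring <- toy_graph(6, lapply(1:6, function(i) c(i, i %% 6 + 1)))
  expect_warning(fpr <- fingerprint(ring), "zero-variance")
  expect_true(all(unclass(fpr)[1, -1] == 0))
  expect_equal(unclass(fpr)[1, 1], 1)
})

test_that("fingerprint dissimilarity is the Frobenius norm of the difference", {
  g <- random_graph(15, 30, rng_seed = 6)
  fa <- fingerprint(g)
  expect_equal(tf_dissimilarity(fa, fa), 0)
  fb <- unclass(fa)
  fb[1, 2] <- fb[2, 1] <- fb[1, 2] + 1
  expect_equal(tf_dissimilarity(fa, fb), sqrt(2))
  expect_equal(tf_dissimilarity(fa, fb), tf_dissimilarity(fb, fa))
  expect_error(tf_dissimilarity(fa, fb[1:5, 1:5]), "shape")
})

test_that("spatial similarity is the node-matched degree correlation", {
  g <- random_graph(20, 50, rng_seed = 7)
  expect_equal(spatial_similarity(g, g), 1)
  comp <- spatial_graph(1 - g$adjacency - diag(1, 20), g$coordinates)
  expect_equal(spatial_similarity(g, comp), -1)  # degree -> n-1-degree
  ring <- toy_graph(6, lapply(1:6, function(i) c(i, i %% 6 + 1)))
  expect_warning(r <- spatial_similarity(ring, ring), "zero degree variance")
  expect_true(is.na(r))
})

test_that("grid search locates sane optima and windows deterministically", {
  coords <- generate_coordinates(20, rng_seed = 8)
  seedg <- suppressMessages(suppressWarnings(make_cohort_seed(coords, rng_seed = 9)))
  target <- simulate_gnm(seedg, 30, "neighbours", gnm_params(-3, 0.2),
                         rng_seed = 10)$final
  grid <- suppressMessages(build_grid(25, c(-5, -1), c(0, 0.4)))
  fit <- grid_search(seedg, target, "neighbours", grid, rng_seed = 11)
  expect_s3_class(fit, "gnm_fit")
  expect_equal(nrow(fit$records), 25)
  # best attains the minimum and beats the median
  expect_equal(fit$best$energy, min(fit$records$energy))
  expect_lte(fit$best$energy, median(fit$records$energy))
  # window bounds contain the best point
  expect_true(fit$best$eta >= fit$top_window$eta[1] &&
              fit$best$eta <= fit$top_window$eta[2])
  # duplicated grid points replay identical rng streams
  dup <- dplyr::bind_rows(grid[3, ], grid[3, ])
  fd <- grid_search(seedg, target, "neighbours", dup, rng_seed = 11)
  expect_equal(fd$records$energy[1], fd$records$energy[2])
  # tidiers
  expect_equal(nrow(tidy(fit)), 25)
  expect_equal(glance(fit)$rule, "neighbours")
})

test_that("cumulative-rank selection orders rules by the three criteria", {
  crit <- tibble::tibble(
    rule = c("A", "B", "C"),
    energy = c(0.10, 0.20, 0.30),            # ranks 1, 2, 3
    tf_dissimilarity = c(0.6, 0.4, 0.9),     # ranks 2, 1, 3
    spatial_r = c(0.5, 0.2, 0.8))            # ranks 2, 3, 1
  rk <- rank_models(crit)
  expect_equal(rk$rule[1], "A")              # rank sum 5 beats 6 and 7
  expect_equal(rk$rank_sum, c(5, 6, 7))
  expect_true(rk$selected[1] && !any(rk$selected[-1]))
  # order invariance
  rk2 <- rank_models(crit[c(3, 1, 2), ])
  expect_equal(rk2$rule[1], "A")
  # a rule best on everything gets the minimal rank sum 3
  crit$energy[2] <- 0.05; crit$tf_dissimilarity[2] <- 0.1; crit$spatial_r[2] <- 0.9
  expect_equal(rank_models(crit)$rule[1], "B")
  expect_equal(rank_models(crit)$rank_sum[1], 3)
  expect_error(rank_models(crit[, -2]), "must contain")
  crit$energy[1] <- NA
  expect_error(rank_models(crit), "missing")
})

test_that("degree-preserving rewiring keeps degrees and stays simple", {
  g <- random_graph(15, 30, rng_seed = 12)
  r <- maslov_sneppen(g, rng_seed = 13)
  expect_equal(rowSums(r$adjacency), rowSums(g$adjacency))
  expect_true(all(diag(r$adjacency) == 0))
  expect_identical(maslov_sneppen(g, rng_seed = 13)$adjacency, r$adjacency)
  expect_false(identical(r$adjacency, g$adjacency))

  # 4-cycle: any accepted swap still yields a simple graph with degrees 2
  cyc <- toy_graph(4, list(c(1, 2), c(2, 3), c(3, 4), c(1, 4)))
  for (s in 1:10) {
    rc <- suppressWarnings(maslov_sneppen(cyc, rng_seed = s))
    expect_equal(rowSums(rc$adjacency), c(2, 2, 2, 2))
    expect_true(all(rc$adjacency %in% c(0L, 1L)))
  }
  one <- toy_graph(3, list(c(1, 2)))
  expect_warning(r1 <- maslov_sneppen(one, rng_seed = 1), "fewer than 2")
  expect_equal(r1$adjacency, one$adjacency)
})
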