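test_that("coordinate sampler gives distinct, reproducible, right-skewed geometry", {
  expect_error(generate_coordinates(2, rng_seed = 1), "at least 3")

  c3 <- generate_coordinates(3, rng_seed = 1)
  d3 <- dist(as.matrix(c3[, c("x", "y", "z")]))
  expect_true(all(d3 > 0))

  a <- generate_coordinates(100, rng_seed = 7)
  b <- generate_coordinates(100, rng_seed = 7)
  expect_identical(a, b)

  # ellipsoidal-shell geometry: the 4,950 pairwise distances are right-skewed
  dv <- as.vector(dist(as.matrix(a[, c("x", "y", "z")])))
  skew <- mean((dv - mean(dv))^3) / sd(dv)^3
  expect_gt(skew, 0)
})

test_that("cohort generator hits the target edge count and keeps the seed", {
  spec <- cohort_spec(n_participants = 5, n_nodes = 30, target_density = 0.10,
                      eta_mean = -3, eta_sd = 0.3, gamma_mean = 0.215,
                      gamma_sd = 0.027, rng_seed = 11)
  coords <- generate_coordinates(30, rng_seed = 2)
  seedg <- suppressMessages(make_cohort_seed(coords, rng_seed = 3))
  cohort <- generate_cohort(spec, seedg)
  # 0.10 * 435 = 43.5 edges rounds to 44 under round-half-to-even
  expect_equal(round(0.10 * 30 * 29 / 2), 44)
  expect_true(all(vapply(cohort$graphs, edge_count, 1) == 44))
  for (g in cohort$graphs)
    expect_true(all(g$adjacency[seedg$adjacency == 1L] == 1L))
  expect_equal(nrow(cohort$truth), 5)

  # degenerate spread: identical parameters, stochastically distinct graphs
  spec0 <- cohort_spec(3, n_nodes = 30, target_density = 0.10,
                       eta_sd = 0, gamma_sd = 0, rng_seed = 4)
  c0 <- generate_cohort(spec0, seedg)
  expect_equal(length(unique(c0$truth$eta)), 1)
  expect_equal(length(unique(c0$truth$gamma)), 1)
  expect_false(identical(c0$graphs[[1]]$adjacency, c0$graphs[[2]]$adjacency))

  dense_seed <- random_graph(30, 100, rng_seed = 9)
  expect_error(generate_cohort(spec, dense_seed), "infeasible")
})

test_that("polygenic scores carry the planted standardized slope", {
  eta <- rnorm(500)
  expect_error(generate_pgs(eta[1:2], 0.5, 1), "at least 3")
  expect_error(generate_pgs(eta, 1.5, 1), "pgs_beta")
  expect_warning(generate_pgs(rep(1, 10), 0.5, 1), "degenerate")

  # perfect-signal limit: slope exactly 1
  s <- generate_pgs(eta, 1, rng_seed = 1)
  expect_equal(unname(cor(s, eta)), 1, tolerance = 1e-12)
  expect_equal(mean(s), 0, tolerance = 1e-12)
  expect_equal(sd(s), 1, tolerance = 1e-12)

  # null: fitted slopes centred on zero across replicates
  slopes0 <- vapply(1:200, function(r) {
    e <- withr::with_seed(r, rnorm(200))
    cor(generate_pgs(e, 0, rng_seed = 1000 + r), e)
  }, numeric(1))
  expect_lt(abs(mean(slopes0)), 3 * sd(slopes0) / sqrt(200))

  # planted effect: mean fitted standardized slope within .01 of .054
  slopes <- vapply(1:500, function(r) {
    e <- withr::with_seed(r, rnorm(1399))
    cor(generate_pgs(e, 0.054, rng_seed = 2000 + r), e)
  }, numeric(1))
  expect_lt(abs(mean(slopes) - 0.054), 0.01)
})

test_that("expression generator plants signal genes at the stated correlation", {
  coords <- generate_coordinates(50, rng_seed = 5)
  map <- coords$x + rnorm(50, sd = 10)

  expect_error(expression_spec(spatial_length_scale = 0), "positive")
  expect_error(expression_spec(n_genes = 5, n_signal_genes = 6), "exceed")

  # perfect-signal limit
  e1 <- generate_expression(expression_spec(50, 3, n_signal_genes = 1,
                                            signal_strength = 1, rng_seed = 1),
                            coords, map)
  expect_equal(abs(cor(e1[, 1], map)), 1, tolerance = 1e-10)

  # null: no signal genes, correlations scattered around zero
  e0 <- generate_expression(expression_spec(50, 200, n_signal_genes = 0,
                                            rng_seed = 2), coords, map)
  r0 <- cor(e0, map)
  expect_lt(abs(mean(r0)), 0.1)

  # planted strength: mean |r| of signal genes near .6 over 100 draws
  rs <- vapply(1:100, function(s) {
    e <- generate_expression(expression_spec(50, 30, n_signal_genes = 25,
                                             signal_strength = 0.6,
                                             rng_seed = s), coords, map)
    mean(abs(cor(e[, attr(e, "signal_genes")], map)))
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.6), 0.05)
})

test_that("cohort files round-trip through a written directory", {
  dir <- withr::local_tempdir()
  spec <- cohort_spec(3, n_nodes = 20, target_density = 0.12, rng_seed = 21)
  coords <- generate_coordinates(20, rng_seed = 22)
  seedg <- suppressMessages(suppressWarnings(make_cohort_seed(coords, rng_seed = 23)))
  cohort <- generate_cohort(spec, seedg)
  write_cohort(cohort, coords, dir)
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  g1 <- read_graph_tsv(file.path(dir, "participant_001.tsv"),
                       read_coordinates_tsv(file.path(dir, "coordinates.tsv")))
  expect_equal(g1$adjacency, cohort$graphs[[1]]$adjacency)
})
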