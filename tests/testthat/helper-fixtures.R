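# Shared fixtures and independent brute-force oracles.

# a spatial graph from an explicit edge list on fixed coordinates
toy_graph <- function(n, edges, rng_seed = 1) {
  coords <- generate_coordinates(n, rng_seed = rng_seed)
  a <- matrix(0L, n, n)
  for (e in edges) {
    a[e[1], e[2]] <- 1L
    a[e[2], e[1]] <- 1L
  }
  spatial_graph(a, coords)
}

# Erdos-Renyi spatial graph with a fixed edge count
random_graph <- function(n, m, rng_seed) {
  withr::with_seed(rng_seed, {
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    pick <- pairs[sample.int(nrow(pairs), m), , drop = FALSE]
    a <- matrix(0L, n, n)
    a[pick] <- 1L
    spatial_graph(a + t(a), generate_coordinates(n, rng_seed = rng_seed))
  })
}

# brute-force two-sample KS by direct CDF evaluation at every pooled point
ks_oracle <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  fa <- vapply(pts, function(x) mean(a <= x), numeric(1))
  fb <- vapply(pts, function(x) mean(b <= x), numeric(1))
  max(abs(fa - fb))
}

# brute-force betweenness: enumerate every shortest path with simple DFS
betweenness_oracle <- function(adj) {
  n <- nrow(adj)
  sp <- function(s, t) { # list of all shortest s->t paths (node sequences)
    best <- list(); bestlen <- Inf
    walk <- function(path) {
      last <- path[length(path)]
      if (last == t) {
        if (length(path) < bestlen) { best <<- list(path); bestlen <<- length(path) }
        else if (length(path) == bestlen) best[[length(best) + 1]] <<- path
        return()
      }
      if (length(path) >= bestlen) return()
      for (nb in which(adj[last, ] == 1)) if (!(nb %in% path)) walk(c(path, nb))
    }
    walk(s)
    best
  }
  btw <- numeric(n)
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    paths <- sp(s, t)
    if (length(paths) == 0) next
    for (p in paths) for (v in setdiff(p, c(s, t)))
      btw[v] <- btw[v] + 1 / length(paths)
  }
  btw
}

# brute-force matching index from explicit neighbour sets
matching_oracle <- function(adj) {
  n <- nrow(adj)
  K <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    ni <- setdiff(which(adj[i, ] == 1), j)
    nj <- setdiff(which(adj[j, ] == 1), i)
    u <- union(ni, nj)
    K[i, j] <- if (length(u) == 0) 0 else length(intersect(ni, nj)) / length(u)
  }
  K
}

# direct evaluation of the Newman Q summation for a given membership
modularity_oracle <- function(adj, membership) {
  m <- sum(adj) / 2
  deg <- rowSums(adj)
  q <- 0
  for (i in seq_len(nrow(adj))) for (j in seq_len(nrow(adj)))
    if (membership[i] == membership[j])
      q <- q + adj[i, j] - deg[i] * deg[j] / (2 * m)
  q / (2 * m)
}

# minimal cohort table for the participant-level statistics
make_cohort_table <- function(n, rng_seed, eta = NULL, pgs = NULL) {
  withr::with_seed(rng_seed, {
    if (is.null(eta)) eta <- rnorm(n, -3.007, 0.336)
    if (is.null(pgs)) pgs <- rnorm(n)
    tibble::tibble(id = seq_len(n), eta = eta,
                   gamma = rnorm(n, 0.215, 0.027), pgs = pgs,
                   sex = sample(c("F", "M"), n, replace = TRUE),
                   age = runif(n, 107, 133), mean_fd = rexp(n, 10))
  })
}
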