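#' Partial-least-squares decoding of a nodal map against gene expression
#'
#' Univariate-response PLS (NIPALS) of a nodal model term (e.g. the
#' parameterised wiring cost of the left-hemisphere regions) on a
#' region x gene expression matrix.  Columns of `X` and `y` are centred
#' and scaled; the sign of each component is fixed so its scores
#' correlate positively with `y`, making gene loadings comparable across
#' participants.
#'
#' @param X region x gene expression matrix with column names, or an
#'   object coercible to one.
#' @param y nodal response vector, one value per region.
#' @param n_components number of latent components (default 3;
#'   `<= min(regions - 1, genes)`).
#' @return a `pls_result`: `loadings` (genes x components structure
#'   correlations, i.e. the correlation of each gene with each component
#'   score — the usual "gene loading" of the imaging-transcriptomics
#'   literature), `x_loadings` (NIPALS projection loadings), `weights`,
#'   `scores`, `y_loadings`, `variance_explained` (per component, fraction
#'   of y variance), `gene_ids`.
#' @export
pls_fit <- function(X, y, n_components = 3) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) abort("rows of `X` must match length of `y`.")
  if (sd(y) == 0) abort("degenerate response: `y` has zero variance.")
  n_components <- min(n_components, nrow(X) - 1, ncol(X))
  if (n_components < 1) abort("need at least one component.")
  gene_ids <- colnames(X)
  if (is.null(gene_ids)) gene_ids <- sprintf("gene%04d", seq_len(ncol(X)))

  xs <- apply(X, 2, sd)
  xs[xs == 0] <- 1 # constant genes stay zero after centring
  Xc <- scale(X, scale = xs)
  yc <- as.numeric(scale(y))
  ssy <- sum(yc^2)

  p <- ncol(Xc); n <- nrow(Xc)
  W <- matrix(0, p, n_components)
  P <- matrix(0, p, n_components)
  Tm <- matrix(0, n, n_components)
  q <- numeric(n_components)
  varex <- numeric(n_components)
  y_res <- yc
  for (h in seq_len(n_components)) {
    w <- drop(crossprod(Xc, y_res))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { n_components <- h - 1L; break }
    w <- w / nw
    t_ <- drop(Xc %*% w)
    tt <- sum(t_^2)
    p_ <- drop(crossprod(Xc, t_)) / tt
    q_ <- sum(y_res * t_) / tt
    # sign convention: scores correlate positively with the original y
    if (cor(t_, yc) < 0) { w <- -w; t_ <- -t_; p_ <- -p_; q_ <- -q_ }
    W[, h] <- w; P[, h] <- p_; Tm[, h] <- t_; q[h] <- q_
    varex[h] <- q_^2 * tt / ssy
    Xc <- Xc - tcrossprod(t_, p_)
    y_res <- y_res - q_ * t_
  }
  if (n_components < 1) abort("no informative component could be extracted.")
  keep <- seq_len(n_components)
  # structure correlations of each (standardized) gene with the scores;
  # constant genes get loading 0
  Xs <- scale(X, scale = xs)
  cl <- suppressWarnings(cor(Xs, Tm[, keep, drop = FALSE]))
  cl[is.na(cl)] <- 0
  structure(list(loadings = `dimnames<-`(cl, list(gene_ids, NULL)),
                 x_loadings = P[, keep, drop = FALSE],
                 weights = W[, keep, drop = FALSE],
                 scores = Tm[, keep, drop = FALSE],
                 y_loadings = q[keep],
                 variance_explained = varex[keep],
                 gene_ids = gene_ids),
            class = "pls_result")
}

#' @export
print.pls_result <- function(x, ...) {
  cat(sprintf("<pls_result> %d genes, %d component(s); y-variance explained: %s\n",
              length(x$gene_ids), ncol(x$loadings),
              paste(sprintf("%.3f", x$variance_explained), collapse = ", ")))
  invisible(x)
}

#' @export
tidy.pls_result <- function(x, ...) {
  tibble::tibble(gene = x$gene_ids, loading = unname(x$loadings[, 1]))
}

#' @export
glance.pls_result <- function(x, ...) {
  tibble::tibble(n_genes = length(x$gene_ids),
                 n_components = ncol(x$loadings),
                 variance_explained_c1 = x$variance_explained[1],
                 variance_explained_total = sum(x$variance_explained))
}

#' Permutation p-values for component-1 gene loadings
#'
#' Permutes the response across regions `n_perm` times, refits the PLS,
#' and scores each gene by how often the null |loading| on component 1
#' reaches the observed one: `p = (1 + #{|null| >= |obs|}) / (n_perm + 1)`.
#'
#' @param X region x gene expression matrix.
#' @param y nodal response vector.
#' @param n_components components for each fit (default 3).
#' @param n_perm number of permutations (>= 100).
#' @param rng_seed integer seed.
#' @return tibble `gene`, `loading` (observed component-1 loading),
#'   `p_value`.
#' @export
permutation_pvalues <- function(X, y, n_components = 3, n_perm = 1000,
                                rng_seed = 1L) {
  if (n_perm < 100) abort("`n_perm` must be at least 100.")
  obs <- pls_fit(X, y, n_components)
  target <- abs(obs$loadings[, 1])
  exceed <- integer(length(target))
  withr::with_seed(rng_seed, {
    for (b in seq_len(n_perm)) {
      null_fit <- pls_fit(X, y[sample.int(length(y))], n_components)
      exceed <- exceed + (abs(null_fit$loadings[, 1]) >= target)
    }
  })
  tibble::tibble(gene = obs$gene_ids, loading = unname(obs$loadings[, 1]),
                 p_value = unname((1 + exceed) / (n_perm + 1)))
}

#' Aggregate per-participant PLS results into a ranked gene list
#'
#' Keeps the genes whose permutation p-value passes `alpha` in every
#' participant (`mode = "all"`, the default) or in at least one
#' (`mode = "any"`), averages their component-1 loadings across
#' participants, and orders by descending mean loading (ties broken
#' lexicographically by gene id).
#'
#' @param results list of tibbles from [permutation_pvalues()] (columns
#'   `gene`, `loading`, `p_value`), one per participant.
#' @param alpha significance threshold (default .05).
#' @param mode `"all"` (intersection) or `"any"` (union) semantics.
#' @return tibble `gene`, `mean_loading`, ordered by descending loading;
#'   empty (with a warning) when no gene survives.
#' @export
aggregate_ranking <- function(results, alpha = 0.05, mode = c("all", "any")) {
  mode <- match.arg(mode)
  if (length(results) < 1) abort("need at least one participant result.")
  combined <- dplyr::bind_rows(results, .id = "participant")
  per_gene <- dplyr::summarise(
    dplyr::group_by(combined, .data$gene),
    n_sig = sum(.data$p_value < alpha),
    n_seen = dplyr::n(),
    mean_loading = mean(.data$loading),
    .groups = "drop")
  keep <- if (mode == "all") {
    per_gene$n_sig == length(results) & per_gene$n_seen == length(results)
  } else {
    per_gene$n_sig >= 1
  }
  out <- per_gene[keep, c("gene", "mean_loading")]
  if (nrow(out) == 0) {
    warn("no gene passed the threshold in the required number of participants.")
    return(tibble::tibble(gene = character(), mean_loading = numeric()))
  }
  dplyr::arrange(out, dplyr::desc(.data$mean_loading), .data$gene)
}
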