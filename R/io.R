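#' Read and write spatial graphs as delimited text
#'
#' Dense tab-separated adjacency matrices plus a separate coordinate
#' table, the exchange format used for cohort directories.
#'
#' @param graph a [spatial_graph()].
#' @param path file path (`.tsv`).
#' @return `write_graph_tsv()` returns `path` invisibly;
#'   `read_graph_tsv()` returns a [spatial_graph()].
#' @export
write_graph_tsv <- function(graph, path) {
  utils::write.table(graph$adjacency, path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_graph_tsv
#' @param coordinates coordinate table for the nodes being read.
#' @export
read_graph_tsv <- function(path, coordinates) {
  adj <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(adj) <- NULL
  spatial_graph(adj, coordinates)
}

#' @rdname write_graph_tsv
#' @param coords coordinate tibble (`node`, `x`, `y`, `z`).
#' @export
write_coordinates_tsv <- function(coords, path) {
  utils::write.table(as.data.frame(coords), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_graph_tsv
#' @export
read_coordinates_tsv <- function(path) {
  tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE))
}

#' Write a synthetic cohort to a directory
#'
#' One adjacency matrix per participant (`participant_<id>.tsv`), the
#' shared coordinates (`coordinates.tsv`), the ground-truth parameter
#' table (`truth.tsv`) and a `manifest.tsv` listing the files.
#'
#' @param cohort list from [generate_cohort()].
#' @param coords coordinate tibble shared by the cohort.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, coords, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- vapply(seq_along(cohort$graphs), function(i) {
    f <- sprintf("participant_%03d.tsv", i)
    write_graph_tsv(cohort$graphs[[i]], file.path(dir, f))
    f
  }, character(1))
  write_coordinates_tsv(coords, file.path(dir, "coordinates.tsv"))
  utils::write.table(as.data.frame(cohort$truth), file.path(dir, "truth.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  manifest <- data.frame(id = cohort$truth$id, file = files)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Write a region-by-gene expression matrix as delimited text
#'
#' @param expr matrix from [generate_expression()].
#' @param path file path (`.tsv`); genes are columns with a header row.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(expr, path) {
  utils::write.table(as.data.frame(expr), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                              check.names = FALSE))
}

#' Write a ranked gene list for ordered enrichment tools
#'
#' @param ranking tibble from [aggregate_ranking()].
#' @param path file path; two tab-separated columns, no header.
#' @return `path`, invisibly.
#' @export
write_ranked_genes <- function(ranking, path) {
  utils::write.table(as.data.frame(ranking), path, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
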