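#' Energy-landscape plot of a grid search
#'
#' @param object a `gnm_fit` from [grid_search()].
#' @param ... ignored.
#' @return a ggplot: eta-gamma tile map coloured by energy, with the best
#'   point marked.
#' @export
autoplot.gnm_fit <- function(object, ...) {
  rec <- dplyr::summarise(dplyr::group_by(object$records, .data$eta, .data$gamma),
                          energy = mean(.data$energy), .groups = "drop")
  ggplot2::ggplot(rec, ggplot2::aes(.data$eta, .data$gamma, fill = .data$energy)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = object$best, shape = 4, colour = "white",
                        size = 3, stroke = 1.2) +
    ggplot2::scale_fill_viridis_c(direction = -1) +
    ggplot2::labs(x = expression(eta), y = expression(gamma), fill = "energy",
                  title = sprintf("Energy landscape (%s rule)", object$rule)) +
    ggplot2::theme_minimal()
}

#' Heatmap of a topological fingerprint
#'
#' @param object a `fingerprint` from [fingerprint()].
#' @param ... ignored.
#' @return a ggplot heatmap of the 6 x 6 metric correlation matrix.
#' @export
autoplot.fingerprint <- function(object, ...) {
  m <- unclass(object)
  dimnames(m) <- list(fingerprint_metrics, fingerprint_metrics)
  df <- tibble::as_tibble(as.data.frame.table(m, responseName = "r"))
  names(df)[1:2] <- c("metric_a", "metric_b")
  ggplot2::ggplot(df, ggplot2::aes(.data$metric_a, .data$metric_b,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)), size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r",
                  title = "Topological fingerprint") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Randomisation-sweep curves
#'
#' @param sweep tibble from [randomisation_sweep()].
#' @return a ggplot of mean global efficiency and mean fingerprint
#'   dissimilarity to the rewired null against the parameter fraction.
#' @export
plot_sweep <- function(sweep) {
  long <- tidyr::pivot_longer(sweep,
                              c("mean_global_efficiency", "mean_tf_dissimilarity"),
                              names_to = "measure", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$fraction, .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "fraction of optimal parameters", y = NULL,
                  title = "Wiring-parameter randomisation sweep") +
    ggplot2::theme_minimal()
}
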