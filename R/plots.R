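#' Plot helpers for sendotype results
#'
#' ggplot2 views of the main result types: `plot_ranking()` shows the
#' top-ranked median absolute loadings coloured by senescence label;
#' `plot_panel_trace()` the silhouette-versus-panel-size trace with the
#' stopping threshold; `plot_cluster_criteria()` the per-k validation
#' criteria (mean silhouette, Calinski-Harabasz, elbow/WSS);
#' `plot_volcano()` the DE volcano; `plot_clinical()` violin contrasts
#' between cohorts.
#'
#' @param ranked A `ranked_features`.
#' @param n_top Number of top proteins to display.
#' @return A ggplot object.
#' @export
plot_ranking <- function(ranked, n_top = 50) {
  stopifnot(inherits(ranked, "ranked_features"))
  d <- head(as_tibble(ranked), n_top)
  d$protein_id <- factor(d$protein_id, levels = rev(d$protein_id))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$median_abs_loading, y = .data$protein_id,
                                  fill = .data$senescent)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2e7d32", `FALSE` = "grey60")) +
    ggplot2::labs(x = "Median |loading| across bootstraps", y = NULL,
                  fill = "Senescence-labelled") +
    ggplot2::theme_minimal()
}

#' @rdname plot_ranking
#' @param panel A `panel_result`.
#' @export
plot_panel_trace <- function(panel) {
  stopifnot(inherits(panel, "panel_result"))
  ggplot2::ggplot(panel$step_trace,
                  ggplot2::aes(x = .data$step, y = .data$silhouette,
                               colour = factor(.data$k))) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = panel$threshold, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = length(panel$panel), linetype = "dotted") +
    ggplot2::labs(x = "Panel size (proteins)", y = "Mean silhouette",
                  colour = "k") +
    ggplot2::theme_minimal()
}

#' @rdname plot_ranking
#' @export
plot_cluster_criteria <- function(panel) {
  stopifnot(inherits(panel, "panel_result"))
  long <- tidyr::pivot_longer(panel$criteria, -"k",
                              names_to = "criterion", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~criterion, scales = "free_y") +
    ggplot2::labs(x = "Number of clusters k", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_ranking
#' @param de A `de_result`.
#' @param alpha BH significance threshold for highlighting.
#' @export
plot_volcano <- function(de, alpha = 0.05) {
  d <- volcano_data(de, alpha = alpha)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log2_fc, y = .data$neg_log10_p,
                                  colour = .data$significant & .data$senescent)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#2e7d32", `FALSE` = "grey50"),
                                 guide = "none") +
    ggplot2::labs(x = "log2 fold change (severe - mild, NPX)",
                  y = expression(-log[10] * "(p)")) +
    ggplot2::theme_minimal()
}

#' @rdname plot_ranking
#' @param clinical A clinical tibble.
#' @param assignment A named `cluster_assignment`.
#' @param variables Clinical variables to show.
#' @export
plot_clinical <- function(clinical, assignment,
                          variables = c("age", "urea", "egfr_baseline",
                                        "egfr_followup", "creatinine_baseline",
                                        "creatinine_followup")) {
  long <- clinical_long(clinical, assignment, variables)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cohort, y = .data$value,
                                     fill = .data$cohort)) +
    ggplot2::geom_violin(alpha = 0.6) +
    ggplot2::geom_boxplot(width = 0.15, outlier.size = 0.5) +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' @rdname plot_ranking
#' @param object Object to autoplot.
#' @param ... Passed to the type-specific plotter.
#' @method autoplot ranked_features
#' @export
autoplot.ranked_features <- function(object, ...) plot_ranking(object, ...)

#' @rdname plot_ranking
#' @method autoplot panel_result
#' @export
autoplot.panel_result <- function(object, ...) plot_panel_trace(object, ...)

#' @rdname plot_ranking
#' @method autoplot de_result
#' @export
autoplot.de_result <- function(object, ...) plot_volcano(object, ...)
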