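#' Broom-style tidiers for sendotyper results
#'
#' `tidy()` returns the per-item table of a result object; `glance()` a
#' one-row summary.
#'
#' @param x A `panel_result`, `cluster_assignment`, `ranked_features` or
#'   `de_result`.
#' @param ... Unused.
#' @return A tibble.
#' @name sendotyper-tidiers
NULL

#' @rdname sendotyper-tidiers
#' @method tidy panel_result
#' @export
tidy.panel_result <- function(x, ...) as_tibble(x$step_trace)

#' @rdname sendotyper-tidiers
#' @method glance panel_result
#' @export
glance.panel_result <- function(x, ...) {
  best <- x$criteria[which.max(x$criteria$mean_silhouette), ]
  tibble(panel_size = length(x$panel), chosen_k = x$chosen_k,
         mean_silhouette = best$mean_silhouette,
         calinski_harabasz = best$calinski_harabasz,
         threshold = x$threshold)
}

#' @rdname sendotyper-tidiers
#' @method tidy cluster_assignment
#' @export
tidy.cluster_assignment <- function(x, ...) as_tibble(x)

#' @rdname sendotyper-tidiers
#' @method glance cluster_assignment
#' @export
glance.cluster_assignment <- function(x, ...) {
  tibble(k = length(unique(x$cluster)), n = nrow(x),
         inertia = attr(x, "inertia"),
         panel_size = length(attr(x, "panel")))
}

#' @rdname sendotyper-tidiers
#' @method tidy ranked_features
#' @export
tidy.ranked_features <- function(x, ...) as_tibble(x)

#' @rdname sendotyper-tidiers
#' @method glance ranked_features
#' @export
glance.ranked_features <- function(x, ...) {
  tibble(n_proteins = nrow(x), selected_pc = attr(x, "selected_pc"),
         n_bootstraps = attr(x, "n_bootstraps"),
         senescent_fraction = mean(x$senescent))
}

#' @rdname sendotyper-tidiers
#' @param alpha Significance threshold used by `glance.de_result()`.
#' @method glance de_result
#' @export
glance.de_result <- function(x, alpha = 0.05, ...) {
  sig <- x$adj_p < alpha
  tibble(n_tested = nrow(x), n_significant = sum(sig),
         n_up = sum(sig & x$log2_fc > 0), n_down = sum(sig & x$log2_fc < 0))
}
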