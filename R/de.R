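#' Welch's two-tailed t-test
#'
#' Unequal-variance two-sample t-test via [stats::t.test()], returned as a
#' one-row tibble. Degenerate inputs where both samples are constant are
#' resolved by the contract: equal means give `t = 0, p = 1`; unequal means
#' give `p = 0` with a warning (infinite evidence at zero variance).
#'
#' @param x,y Numeric vectors (>= 2 values each).
#' @return A tibble with `t_stat`, `df` (Welch-Satterthwaite), `p_value`.
#' @export
welch_t_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) abort("Welch test needs >= 2 values per group.")
  if (sd(x) == 0 && sd(y) == 0) {
    if (mean(x) == mean(y)) return(tibble(t_stat = 0, df = length(x) + length(y) - 2,
                                          p_value = 1))
    warn("Both groups constant with different means; p = 0.")
    return(tibble(t_stat = sign(mean(x) - mean(y)) * Inf,
                  df = length(x) + length(y) - 2, p_value = 0))
  }
  fit <- t.test(x, y, var.equal = FALSE, alternative = "two.sided")
  tibble(t_stat = unname(fit$statistic), df = unname(fit$parameter),
         p_value = fit$p.value)
}

#' Log2 fold change between cohorts on NPX data
#'
#' NPX is already log2-scale, so the difference of group means *is* the log2
#' fold change: `mean(severe) - mean(mild)`.
#'
#' @param severe,mild Numeric NPX vectors.
#' @return The difference of means.
#' @export
log2_fold_change <- function(severe, mild) {
  mean(severe, na.rm = TRUE) - mean(mild, na.rm = TRUE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR control via [stats::p.adjust()]; order-preserving and
#' monotone.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) p.adjust(p, method = "BH")

#' Differential expression between sendotype cohorts
#'
#' Welch two-tailed t-test per protein between the severe and mild cohorts of
#' a named cluster assignment, with BH adjustment across proteins, log2 fold
#' change as the severe-minus-mild NPX mean difference, and senescence flags.
#'
#' @param x A complete NPX tibble.
#' @param assignment A `cluster_assignment` with a `cohort` column (see
#'   [name_cohorts()]), or any data frame with `patient_id` and `cohort`
#'   columns containing `"severe"` and `"mild"`.
#' @param senescence Character vector of senescence-labelled symbols, or
#'   `NULL`.
#' @return A tibble of class `de_result`: `protein_id`, `log2_fc`, `t_stat`,
#'   `df`, `p_value`, `adj_p`, `senescent`, ordered by `p_value`.
#' @export
de_table <- function(x, assignment, senescence = NULL) {
  stopifnot(is.data.frame(assignment), all(c("patient_id", "cohort") %in% names(assignment)))
  m <- npx_matrix(x)
  assignment <- assignment[assignment$cohort %in% c("mild", "severe"), ]
  sev_ids <- assignment$patient_id[assignment$cohort == "severe"]
  mild_ids <- assignment$patient_id[assignment$cohort == "mild"]
  if (length(sev_ids) < 2 || length(mild_ids) < 2) {
    abort("Need >= 2 patients in each of the mild and severe cohorts.")
  }
  sev <- m[sev_ids, , drop = FALSE]
  mild <- m[mild_ids, , drop = FALSE]
  rows <- purrr::map_dfr(colnames(m), function(pr) {
    wt <- welch_t_test(sev[, pr], mild[, pr])
    tibble(protein_id = pr, log2_fc = log2_fold_change(sev[, pr], mild[, pr]),
           t_stat = wt$t_stat, df = wt$df, p_value = wt$p_value)
  })
  rows$adj_p <- bh_adjust(rows$p_value)
  rows$senescent <- if (is.null(senescence)) FALSE else rows$protein_id %in% senescence
  rows <- rows[order(rows$p_value, rows$protein_id), ]
  structure(rows, class = c("de_result", class(tibble())))
}

#' Volcano- and heatmap-ready exports of a DE table
#'
#' `volcano_data()` returns `protein_id`, `log2_fc`, `neg_log10_p`,
#' `significant` (BH < alpha), `senescent`. `heatmap_data()` returns the top
#' `n_top` proteins by p-value as a long tibble of per-protein z-scored NPX
#' with patients ordered by cohort, ready for tile plotting or writing.
#'
#' @param de A `de_result`.
#' @param alpha Significance threshold on the adjusted p-value.
#' @return A tibble.
#' @export
volcano_data <- function(de, alpha = 0.05) {
  stopifnot(inherits(de, "de_result"))
  tibble(protein_id = de$protein_id, log2_fc = de$log2_fc,
         neg_log10_p = -log10(pmax(de$p_value, .Machine$double.xmin)),
         significant = de$adj_p < alpha, senescent = de$senescent)
}

#' @rdname volcano_data
#' @param x The NPX tibble the DE was computed from.
#' @param assignment The named cluster assignment used.
#' @param n_top Number of top proteins (by p-value) to include.
#' @export
heatmap_data <- function(de, x, assignment, n_top = 25) {
  stopifnot(inherits(de, "de_result"))
  top <- head(de$protein_id, n_top)
  m <- npx_matrix(x)[, top, drop = FALSE]
  z <- zscore_safe(m, scale = TRUE)
  ord <- assignment[order(assignment$cohort, assignment$patient_id), ]
  long <- as_tibble(z[ord$patient_id, , drop = FALSE], rownames = "patient_id") %>%
    tidyr::pivot_longer(-"patient_id", names_to = "protein_id", values_to = "z_npx") %>%
    left_join(ord[c("patient_id", "cohort")], by = "patient_id")
  long$patient_id <- factor(long$patient_id, levels = ord$patient_id)
  long$protein_id <- factor(long$protein_id, levels = rev(top))
  long
}
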