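#' Hypergeometric over-representation analysis
#'
#' Tests each gene set for over-representation of a query symbol set against
#' a background universe (by default the assayed, post-QC proteins — the
#' measured background, not the whole genome). The p-value is the
#' hypergeometric upper tail `P[X >= k]` with `K` set members among `N`
#' universe symbols and `n` query draws; fold enrichment is
#' `(k/n) / (K/N)`. BH adjustment is applied across terms. Symbols outside
#' the universe are ignored on both sides, so results are invariant to them.
#' Terms with no universe overlap are skipped (logged via `message()`).
#'
#' @param query Character vector of significant symbols (non-empty after
#'   intersection with the universe).
#' @param gene_sets A gene-set tibble from [read_gmt()] (columns `term_id`,
#'   `description`, `genes` list-column).
#' @param universe Character vector of background symbols.
#' @return A tibble of class `ora_result`, sorted by p-value: `term_id`,
#'   `description`, `k` (overlap), `set_size`, `query_size`, `universe_size`,
#'   `fold_enrichment`, `p_value`, `adj_p`.
#' @export
ora <- function(query, gene_sets, universe) {
  stopifnot(is.data.frame(gene_sets),
            all(c("term_id", "description", "genes") %in% names(gene_sets)))
  universe <- unique(universe)
  query <- unique(intersect(query, universe))
  if (length(query) == 0) abort("Query is empty (after intersection with the universe).")
  N <- length(universe)
  n <- length(query)
  rows <- purrr::map_dfr(seq_len(nrow(gene_sets)), function(i) {
    members <- intersect(gene_sets$genes[[i]], universe)
    K <- length(members)
    if (K == 0) {
      message("ORA: term '", gene_sets$term_id[i], "' has no universe overlap; skipped.")
      return(NULL)
    }
    k <- length(intersect(members, query))
    tibble(term_id = gene_sets$term_id[i], description = gene_sets$description[i],
           k = k, set_size = K, query_size = n, universe_size = N,
           fold_enrichment = (k / n) / (K / N),
           p_value = phyper(k - 1, K, N - K, n, lower.tail = FALSE))
  })
  if (nrow(rows) == 0) abort("No gene set overlaps the universe.")
  rows$adj_p <- bh_adjust(rows$p_value)
  rows <- rows[order(rows$p_value, rows$term_id), ]
  structure(rows, class = c("ora_result", class(tibble())))
}

#' Significant symbols from a DE table
#'
#' Filters a [de_table()] result to the symbols below the significance
#' threshold, the query an over-representation analysis consumes.
#'
#' @param de A `de_result`.
#' @param alpha Significance threshold (default 0.05).
#' @param use_adjusted Filter on BH-adjusted p (default) or raw p.
#' @return Character vector of significant symbols (possibly empty).
#' @export
de_to_query <- function(de, alpha = 0.05, use_adjusted = TRUE) {
  stopifnot(inherits(de, "de_result"))
  p <- if (use_adjusted) de$adj_p else de$p_value
  de$protein_id[p < alpha]
}
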