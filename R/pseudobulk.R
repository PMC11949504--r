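#' Cell-type pseudobulk aggregation
#'
#' Sums single-cell counts over cells within each (sample, cell type) pair —
#' one pseudobulk row per patient per cell type — so sample-level
#' differential expression can be run on cell-type-resolved profiles.
#' Samples with zero cells of a type simply contribute no row for that type.
#'
#' @param x A `sendotype_counts` object, or a cells x genes matrix
#'   (sparse or dense) passed with `cells` annotations.
#' @param cells A tibble with `cell_id`, `sample_id`, `cell_type` and
#'   (optionally) `condition`, aligned to the matrix rows; defaults to the
#'   annotations carried by `x`.
#' @return A list of class `pseudobulk`: `counts` (rows = sample:cell_type,
#'   columns = genes, integer sums), `samples` (tibble: row_id, sample_id,
#'   cell_type, condition, n_cells).
#' @export
pseudobulk_aggregate <- function(x, cells = NULL) {
  if (inherits(x, "sendotype_counts")) {
    if (is.null(cells)) cells <- x$cells
    x <- x$counts
  }
  stopifnot(!is.null(cells), all(c("cell_id", "sample_id", "cell_type") %in% names(cells)))
  m <- as.matrix(x)
  if (is.null(rownames(m))) rownames(m) <- cells$cell_id
  cells <- cells[match(rownames(m), cells$cell_id), ]
  if (anyNA(cells$sample_id)) abort("Every cell must be annotated with a sample_id.")
  if (!is.null(cells$condition)) {
    map <- unique(cells[c("sample_id", "condition")])
    if (anyDuplicated(map$sample_id)) abort("sample -> condition mapping must be single-valued.")
  }
  group <- paste(cells$sample_id, cells$cell_type, sep = ":")
  agg <- rowsum(m, group)
  samples <- unique(tibble(row_id = group, sample_id = cells$sample_id,
                           cell_type = cells$cell_type,
                           condition = if (is.null(cells$condition)) NA_character_
                                       else cells$condition))
  samples$n_cells <- as.integer(table(group)[samples$row_id])
  samples <- samples[match(rownames(agg), samples$row_id), ]
  structure(list(counts = agg, samples = samples), class = "pseudobulk")
}

#' Counts-per-million and transcripts-per-million transforms
#'
#' `cpm()` scales each row to sum to one million: `c / sum(c) * 1e6`.
#' `tpm()` first divides by gene length (`(c/L) / sum(c/L) * 1e6`), so
#' equal lengths make TPM identical to CPM; with no lengths supplied, TPM
#' falls back to CPM with a warning.
#'
#' @param counts A matrix (rows = samples) or vector of non-negative counts.
#' @param gene_lengths Gene lengths in bases, recycled across rows, or
#'   `NULL`.
#' @return A matrix (or vector) of per-million values.
#' @export
cpm <- function(counts) {
  v <- is.null(dim(counts))
  m <- if (v) matrix(counts, 1) else as.matrix(counts)
  totals <- rowSums(m)
  if (any(totals == 0)) {
    abort("Row with zero total counts; remove low-expression samples first.")
  }
  out <- m / totals * 1e6
  if (v) drop(out) else out
}

#' @rdname cpm
#' @export
tpm <- function(counts, gene_lengths = NULL) {
  if (is.null(gene_lengths)) {
    warn("No gene lengths supplied; TPM falls back to CPM.")
    return(cpm(counts))
  }
  v <- is.null(dim(counts))
  m <- if (v) matrix(counts, 1) else as.matrix(counts)
  if (length(gene_lengths) != ncol(m)) abort("gene_lengths must match the number of genes.")
  if (any(gene_lengths <= 0)) abort("Gene lengths must be positive.")
  rate <- sweep(m, 2, gene_lengths, "/")
  totals <- rowSums(rate)
  if (any(totals == 0)) abort("Row with zero total counts; remove low-expression samples first.")
  out <- rate / totals * 1e6
  if (v) drop(out) else out
}

#' Remove samples with very low overall expression
#'
#' Drops every sample for which *any* of its cell-type pseudobulk rows has a
#' total count below `min_total` — a starved cell-type profile makes all of
#' that patient's per-million values unreliable. Removals are logged.
#'
#' @param pb A `pseudobulk` object.
#' @param min_total Minimum summed counts per (sample, cell type) row.
#' @param verbose Log removed sample ids.
#' @return The filtered `pseudobulk`, with attribute `removed_samples`.
#' @export
remove_low_expression <- function(pb, min_total = 50000, verbose = TRUE) {
  stopifnot(inherits(pb, "pseudobulk"))
  totals <- rowSums(pb$counts)
  starved <- unique(pb$samples$sample_id[totals < min_total])
  keep <- !(pb$samples$sample_id %in% starved)
  if (!any(keep)) abort("Every sample falls below min_total; threshold too high.")
  if (verbose && length(starved) > 0) {
    message("Removed low-expression samples: ", paste(starved, collapse = ", "))
  }
  out <- structure(list(counts = pb$counts[keep, , drop = FALSE],
                        samples = pb$samples[keep, , drop = FALSE]),
                   class = "pseudobulk")
  attr(out, "removed_samples") <- starved
  out
}

#' Pseudobulk differential expression between conditions
#'
#' Within each cell type, Welch-tests `log2(TPM + 1)` per gene between case
#' and control samples, with BH adjustment within the cell type and log2
#' fold change as the case-minus-control mean difference on that scale. This
#' keeps a single DE engine across the proteomic and transcriptomic stages.
#'
#' @param pb A `pseudobulk` with a `condition` column (`"case"`/`"control"`).
#' @param gene_lengths Optional gene lengths for the TPM transform.
#' @param by_cell_type Test within each cell type (default) or pooled.
#' @return A tibble of class `de_result` with columns `cell_type`, `gene_id`,
#'   `log2_fc`, `t_stat`, `df`, `p_value`, `adj_p`.
#' @export
pseudobulk_de <- function(pb, gene_lengths = NULL, by_cell_type = TRUE) {
  stopifnot(inherits(pb, "pseudobulk"))
  if (anyNA(pb$samples$condition)) abort("pseudobulk_de needs a condition annotation.")
  norm <- if (is.null(gene_lengths)) cpm(pb$counts) else tpm(pb$counts, gene_lengths)
  expr <- log2(norm + 1)
  groups <- if (by_cell_type) split(seq_len(nrow(expr)), pb$samples$cell_type)
            else list(all = seq_len(nrow(expr)))
  rows <- purrr::map_dfr(names(groups), function(ct) {
    idx <- groups[[ct]]
    cond <- pb$samples$condition[idx]
    case <- expr[idx[cond == "case"], , drop = FALSE]
    ctrl <- expr[idx[cond == "control"], , drop = FALSE]
    if (nrow(case) < 2 || nrow(ctrl) < 2) {
      abort(paste0("Cell type '", ct, "' has < 2 samples in a condition."))
    }
    res <- purrr::map_dfr(colnames(expr), function(g) {
      wt <- welch_t_test(case[, g], ctrl[, g])
      tibble(cell_type = ct, gene_id = g,
             log2_fc = log2_fold_change(case[, g], ctrl[, g]),
             t_stat = wt$t_stat, df = wt$df, p_value = wt$p_value)
    })
    res$adj_p <- bh_adjust(res$p_value)
    res
  })
  rows <- rows[order(rows$p_value, rows$gene_id), ]
  structure(rows, class = c("de_result", class(tibble())))
}
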