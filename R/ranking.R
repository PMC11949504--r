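# Centre columns; divide by SD where it is positive, leaving constant
# columns at zero so they carry no loading instead of breaking the scaling.
zscore_safe <- function(m, scale = TRUE) {
  m <- sweep(m, 2, colMeans(m), "-")
  if (scale) {
    s <- apply(m, 2, sd)
    s[s == 0] <- 1
    m <- sweep(m, 2, s, "/")
  }
  m
}

#' Principal component analysis of an NPX matrix
#'
#' Thin wrapper over [stats::prcomp()] with NPX-appropriate preprocessing:
#' proteins are centred and (by default) z-scored, with zero-variance
#' proteins left at zero rather than erroring, so constant assays simply get
#' zero loadings. Loading vectors are unit-norm columns; explained variances
#' are non-increasing.
#'
#' @param x An NPX tibble (complete; impute first) or numeric matrix.
#' @param n_components Number of components to keep (default all).
#' @param scale Z-score proteins before PCA (default `TRUE`; unscaled PCA
#'   ranks proteins by variance rather than class signal).
#' @return A list of class `npx_pca`: `loadings` (proteins x PCs), `scores`
#'   (patients x PCs), `explained_variance`, `explained_variance_ratio`.
#' @export
pca_loadings <- function(x, n_components = NULL, scale = TRUE) {
  m <- if (is.matrix(x)) x else npx_matrix(x)
  if (anyNA(m)) abort("NPX matrix has missing values; run impute_missing() first.")
  z <- zscore_safe(m, scale = scale)
  if (all(abs(z) < .Machine$double.eps^0.5)) abort("Zero-variance matrix: PCA undefined.")
  k_max <- min(nrow(m) - 1L, ncol(m))
  k <- if (is.null(n_components)) k_max else min(as.integer(n_components), k_max)
  fit <- prcomp(z, center = FALSE, scale. = FALSE)
  structure(list(
    loadings = fit$rotation[, seq_len(k), drop = FALSE],
    scores = fit$x[, seq_len(k), drop = FALSE],
    explained_variance = fit$sdev[seq_len(k)]^2,
    explained_variance_ratio = fit$sdev[seq_len(k)]^2 / sum(fit$sdev^2),
    scale = scale
  ), class = "npx_pca")
}

# One-way ANOVA F statistic of a numeric vector across >= 2 groups.
anova_f <- function(x, g) {
  g <- droplevels(as.factor(g))
  ns <- tabulate(g)
  k <- length(ns)
  if (k < 2) abort("select_pc needs at least two classes.")
  gm <- mean(x)
  means <- tapply(x, g, mean)
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum(tapply(x, g, function(v) sum((v - mean(v))^2)))
  n <- length(x)
  if (ssw == 0) return(if (ssb == 0) 0 else Inf)
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' Select the principal component spanning the most class variance
#'
#' Among the first `n_candidates` PCs, returns the index whose scores
#' maximise the one-way ANOVA F statistic across the class labels (e.g. CKD
#' severity groups). Ties break toward the lower index; with no labels, PC1
#' is returned with a warning.
#'
#' @param pca An `npx_pca` fit, or a scores matrix.
#' @param labels Per-patient class labels (>= 2 classes), or `NULL`.
#' @param n_candidates How many leading PCs to consider.
#' @return The selected PC index (integer).
#' @export
select_pc <- function(pca, labels, n_candidates = 10) {
  scores <- if (inherits(pca, "npx_pca")) pca$scores else as.matrix(pca)
  if (is.null(labels)) {
    warn("No class labels supplied; defaulting to PC1.")
    return(1L)
  }
  labels <- as.factor(as.character(labels))
  if (nlevels(droplevels(labels)) < 2) abort("select_pc needs at least two classes.")
  if (length(labels) != nrow(scores)) abort("labels length must match number of patients.")
  idx <- seq_len(min(n_candidates, ncol(scores)))
  f <- vapply(idx, function(j) anova_f(scores[, j], labels), numeric(1))
  as.integer(which.max(f)) # which.max takes the first maximum: low-index ties
}

#' Rank proteins by bootstrapped PCA loading magnitude
#'
#' For each of `n_bootstraps` bootstrap resamples of the patients (with
#' replacement, full cohort size), fits a PCA, picks the component spanning
#' the most class variance via [select_pc()], sign-aligns that bootstrap
#' loading vector to the full-data one (flipping if anti-correlated, so the
#' median is not biased toward zero by arbitrary PC signs), and records the
#' absolute loadings. Proteins are ranked by their per-protein **median
#' absolute loading**, descending; direction is deliberately ignored. Each
#' protein is flagged by membership in the senescence label set.
#'
#' @param x A complete NPX tibble.
#' @param labels Per-patient class labels for [select_pc()] (e.g. severity).
#' @param senescence Character vector of senescence-labelled symbols (or
#'   `NULL`: all flags `FALSE`, with a warning downstream in
#'   [top_k_senescent_fraction()]).
#' @param n_bootstraps Number of bootstrap resamples (>= 1).
#' @param n_candidates PCs scanned by [select_pc()].
#' @param scale Z-score proteins before PCA.
#' @param resample Test hook: `FALSE` fits each "bootstrap" on the original
#'   cohort, so the ranking equals the plain PCA |loading|.
#' @param case_fold Case-insensitive senescence matching.
#' @param seed Integer seed for the resampling.
#' @return A tibble of class `ranked_features`, ordered by
#'   `median_abs_loading` descending (ties by protein id), with columns
#'   `rank`, `protein_id`, `median_abs_loading`, `senescent`; attributes
#'   `selected_pc` (full-data choice) and `n_bootstraps`.
#' @export
bootstrap_rank <- function(x, labels, senescence = NULL, n_bootstraps = 500,
                           n_candidates = 10, scale = TRUE, resample = TRUE,
                           case_fold = FALSE, seed = 1) {
  m <- npx_matrix(x)
  if (anyNA(m)) abort("NPX matrix has missing values; run impute_missing() first.")
  stopifnot(n_bootstraps >= 1)
  n <- nrow(m)
  full <- pca_loadings(m, n_components = n_candidates, scale = scale)
  pc_full <- select_pc(full, labels, n_candidates)
  ref <- full$loadings[, pc_full]

  abs_loadings <- matrix(NA_real_, ncol(m), n_bootstraps,
                         dimnames = list(colnames(m), NULL))
  withr::with_seed(as.integer(seed), {
    for (b in seq_len(n_bootstraps)) {
      v <- NULL
      for (try in seq_len(10)) {
        idx <- if (resample) sample.int(n, n, replace = TRUE) else seq_len(n)
        v <- tryCatch({
          fit <- pca_loadings(m[idx, , drop = FALSE], n_components = n_candidates,
                              scale = scale)
          pc_b <- select_pc(fit, labels[idx], n_candidates)
          fit$loadings[, pc_b]
        }, error = function(e) NULL)
        if (!is.null(v)) break
        if (try == 10) abort("Bootstrap failed 10 times (degenerate resamples).")
      }
      if (sum(v * ref) < 0) v <- -v # sign alignment before |.|
      abs_loadings[, b] <- abs(v)
    }
  })
  med <- unname(apply(abs_loadings, 1, median))
  sen_set <- if (case_fold) toupper(senescence) else senescence
  ids <- colnames(m)
  sen <- if (is.null(senescence)) rep(FALSE, length(ids)) else
    (if (case_fold) toupper(ids) else ids) %in% sen_set
  out <- tibble(protein_id = ids, median_abs_loading = med, senescent = sen)
  out <- out[order(-out$median_abs_loading, out$protein_id), ]
  out$rank <- seq_len(nrow(out))
  out <- out[c("rank", "protein_id", "median_abs_loading", "senescent")]
  structure(out, class = c("ranked_features", class(tibble())),
            selected_pc = pc_full, n_bootstraps = as.integer(n_bootstraps))
}

#' Senescence-label fraction among the top-ranked proteins
#'
#' @param ranked A `ranked_features` tibble from [bootstrap_rank()].
#' @param k Number of top ranks to consider (`k <=` number of proteins).
#' @return The fraction of the top `k` proteins flagged senescent.
#' @export
top_k_senescent_fraction <- function(ranked, k) {
  stopifnot(inherits(ranked, "ranked_features"))
  if (k > nrow(ranked)) abort("k exceeds the number of ranked proteins.")
  if (!any(ranked$senescent)) {
    warn("No senescence labels among ranked proteins; fraction is 0.")
    return(0)
  }
  mean(ranked$senescent[seq_len(k)])
}
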