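panel_matrix <- function(x, panel, scale = TRUE) {
  m <- npx_matrix(x)
  missing <- setdiff(panel, colnames(m))
  if (length(missing) > 0) {
    abort(paste0("Panel proteins absent from NPX matrix: ", paste(missing, collapse = ", ")))
  }
  m <- m[, panel, drop = FALSE]
  if (scale) zscore_safe(m) else m
}

#' K-means clustering of patients on a protein panel
#'
#' Runs [stats::kmeans()] (Hartigan-Wong, `n_restarts` random starts, best
#' restart by total within-cluster sum of squares) on the z-scored panel
#' sub-matrix and returns a tidy per-patient assignment.
#'
#' @param x A complete NPX tibble.
#' @param panel Character vector of protein ids to cluster on (default: all).
#' @param k Number of clusters (>= 2; `k = 1` is allowed as a degenerate
#'   case for closed-form checks).
#' @param n_restarts,max_iter K-means restarts and iteration cap.
#' @param scale Z-score panel proteins before clustering.
#' @param seed Integer seed for the restarts.
#' @return A tibble of class `cluster_assignment` with columns `patient_id`,
#'   `cluster` (integer); attributes `centroids` (k x p), `inertia` (total
#'   within-cluster SS), `panel`, and later `cohort` names from
#'   [name_cohorts()].
#' @export
cluster_kmeans <- function(x, panel = NULL, k = 2, n_restarts = 25,
                           max_iter = 300, scale = TRUE, seed = 1) {
  if (is.null(panel)) panel <- npx_proteins(x)
  z <- panel_matrix(x, panel, scale = scale)
  if (anyNA(z)) abort("NPX matrix has missing values; run impute_missing() first.")
  if (k > nrow(z)) abort("k cannot exceed the number of patients.")
  if (k < 1) abort("k must be at least 1.")
  fit <- withr::with_seed(as.integer(seed),
    kmeans(z, centers = k, nstart = n_restarts, iter.max = max_iter))
  out <- tibble(patient_id = rownames(z), cluster = as.integer(fit$cluster))
  structure(out, class = c("cluster_assignment", class(tibble())),
            centroids = fit$centers, inertia = fit$tot.withinss,
            panel = panel, scale = scale)
}

#' Mean silhouette coefficient
#'
#' For each point, `a` is its mean Euclidean distance to the other members of
#' its own cluster and `b` the smallest mean distance to any other cluster;
#' the silhouette is `(b - a) / max(a, b)`, with singletons scoring 0. The
#' cohort mean (in \[-1, 1\]) gauges clustering quality; the panel-selection
#' stopping rule requires it to stay at or above 0.5.
#'
#' @param x Numeric matrix (observations x features), already on the scale
#'   clustering was done on.
#' @param labels Cluster labels (>= 2 distinct values).
#' @return Mean silhouette coefficient.
#' @export
silhouette_score <- function(x, labels) {
  mean(silhouette_widths(x, labels))
}

#' @rdname silhouette_score
#' @return `silhouette_widths()`: the per-point silhouette values.
#' @export
silhouette_widths <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.integer(as.factor(labels))
  if (length(labels) != nrow(x)) abort("labels length must match rows of x.")
  if (length(unique(labels)) < 2) abort("Silhouette needs at least 2 clusters.")
  d <- as.matrix(dist(x))
  n <- nrow(x)
  ks <- sort(unique(labels))
  # mean distance from every point to every cluster
  mean_to <- vapply(ks, function(k) rowSums(d[, labels == k, drop = FALSE]) /
                      pmax(1, sum(labels == k) - (labels == k)), numeric(n))
  # rowSums over own cluster includes d(i,i)=0; divisor excludes self
  sw <- numeric(n)
  for (i in seq_len(n)) {
    own <- match(labels[i], ks)
    size_own <- sum(labels == labels[i])
    if (size_own == 1) { sw[i] <- 0; next }
    a <- mean_to[i, own]
    b <- min(mean_to[i, -own])
    sw[i] <- (b - a) / max(a, b)
  }
  sw
}

#' Calinski-Harabasz index
#'
#' Ratio of between- to within-cluster dispersion scaled by degrees of
#' freedom: `(SSB / (k - 1)) / (SSW / (n - k))`. Larger is better; on
#' unstructured data it hovers near 1.
#'
#' @inheritParams silhouette_score
#' @return The index (>= 0).
#' @export
calinski_harabasz <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.factor(labels)
  n <- nrow(x)
  k <- nlevels(droplevels(labels))
  if (k < 2) abort("Calinski-Harabasz needs at least 2 clusters.")
  if (k >= n) abort("Calinski-Harabasz needs n > k.")
  centre <- colMeans(x)
  ssb <- 0; ssw <- 0
  for (lev in levels(droplevels(labels))) {
    xi <- x[labels == lev, , drop = FALSE]
    ci <- colMeans(xi)
    ssb <- ssb + nrow(xi) * sum((ci - centre)^2)
    ssw <- ssw + sum(sweep(xi, 2, ci, "-")^2)
  }
  if (ssw == 0) return(Inf)
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' Within-cluster sum of squares for a labelling
#' @inheritParams silhouette_score
#' @return Total within-cluster sum of squares (NPX^2 units).
#' @export
wss <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.factor(labels)
  total <- 0
  for (lev in levels(droplevels(labels))) {
    xi <- x[labels == lev, , drop = FALSE]
    total <- total + sum(sweep(xi, 2, colMeans(xi), "-")^2)
  }
  total
}

#' Silhouette-constrained forward panel selection
#'
#' Grows a protein panel along the bootstrap ranking, one protein per step.
#' At each step, k-means is run for every `k` in `k_range` and the mean
#' silhouette recorded; a step *passes* if its best-over-k silhouette is at
#' least `threshold`. The returned panel is the longest passing prefix: the
#' largest protein set that still clusters patients effectively. Growth stops
#' once `patience` consecutive steps fail (silhouette decays monotonically as
#' uninformative proteins dilute the panel) or at `max_panel` proteins. For
#' the final panel the three cluster-validation criteria (mean silhouette,
#' Calinski-Harabasz, within-cluster SS for the elbow) are reported per k,
#' and `chosen_k` maximises the mean silhouette.
#'
#' @param ranked A `ranked_features` tibble.
#' @param x The complete NPX tibble the ranking came from.
#' @param k_range Candidate cluster numbers (default 2:10).
#' @param threshold Silhouette stopping threshold (default 0.5).
#' @param max_panel Cap on panel size (default `min(40, n proteins)`).
#' @param patience Consecutive failing steps tolerated before stopping.
#' @param n_restarts K-means restarts per fit.
#' @param scale Z-score panel proteins before clustering.
#' @param seed Integer seed.
#' @return A list of class `panel_result`: `panel` (ordered ids), `chosen_k`,
#'   `step_trace` (tibble: step, k, silhouette), `criteria` (tibble: k,
#'   mean_silhouette, calinski_harabasz, wss), `threshold`.
#' @export
forward_panel_selection <- function(ranked, x, k_range = 2:10, threshold = 0.5,
                                    max_panel = NULL, patience = 5,
                                    n_restarts = 25, scale = TRUE, seed = 1) {
  stopifnot(inherits(ranked, "ranked_features"))
  if (nrow(ranked) == 0) abort("Ranked list is empty.")
  m <- npx_matrix(x)
  if (anyNA(m)) abort("NPX matrix has missing values; run impute_missing() first.")
  if (is.null(max_panel)) max_panel <- min(40L, nrow(ranked))
  max_panel <- min(max_panel, nrow(ranked))
  k_range <- k_range[k_range >= 2 & k_range <= nrow(m) - 1]

  trace <- list()
  pass <- logical(0)
  fails <- 0L
  withr::with_seed(as.integer(seed), {
    for (step in seq_len(max_panel)) {
      panel <- ranked$protein_id[seq_len(step)]
      z <- m[, panel, drop = FALSE]
      if (scale) z <- zscore_safe(z)
      sil <- vapply(k_range, function(k) {
        fit <- kmeans(z, centers = k, nstart = n_restarts, iter.max = 300)
        silhouette_score(z, fit$cluster)
      }, numeric(1))
      trace[[step]] <- tibble(step = step, k = k_range, silhouette = sil)
      pass[step] <- max(sil) >= threshold
      fails <- if (pass[step]) 0L else fails + 1L
      if (fails >= patience) break
    }
  })
  step_trace <- dplyr::bind_rows(trace)
  if (!any(pass)) {
    abort(sprintf(
      "No panel prefix reached silhouette >= %.2f (best %.3f); no effective clustering.",
      threshold, max(step_trace$silhouette)))
  }
  n_panel <- max(which(pass))
  panel <- ranked$protein_id[seq_len(n_panel)]

  z <- m[, panel, drop = FALSE]
  if (scale) z <- zscore_safe(z)
  criteria <- withr::with_seed(as.integer(seed) + 1L, {
    purrr::map_dfr(k_range, function(k) {
      fit <- kmeans(z, centers = k, nstart = n_restarts, iter.max = 300)
      tibble(k = k,
             mean_silhouette = silhouette_score(z, fit$cluster),
             calinski_harabasz = calinski_harabasz(z, fit$cluster),
             wss = fit$tot.withinss)
    })
  })
  chosen_k <- criteria$k[which.max(criteria$mean_silhouette)]
  structure(list(panel = panel, chosen_k = as.integer(chosen_k),
                 step_trace = step_trace, criteria = criteria,
                 threshold = threshold),
            class = "panel_result")
}

#' Name clusters as mild / severe cohorts
#'
#' The cluster with the higher mean panel NPX is the severe cohort (the
#' panel proteins are upregulated with severity); the lowest-mean cluster is
#' mild. With more than two clusters the intermediates are named
#' `intermediate-1`, ... by increasing mean. Exact ties break toward the
#' lower cluster index being mild, with a warning.
#'
#' @param assignment A `cluster_assignment`.
#' @param x The NPX tibble clustered on.
#' @param panel Protein ids defining the panel (default: the assignment's).
#' @return The assignment with a `cohort` column added and a `cohort_names`
#'   attribute (cluster -> name map).
#' @export
name_cohorts <- function(assignment, x, panel = NULL) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  if (is.null(panel)) panel <- attr(assignment, "panel")
  m <- npx_matrix(x)[assignment$patient_id, panel, drop = FALSE]
  cl <- sort(unique(assignment$cluster))
  means <- vapply(cl, function(k) mean(m[assignment$cluster == k, ]), numeric(1))
  if (anyDuplicated(means)) warn("Cluster mean panel NPX tie; lower cluster index named mild.")
  ord <- order(means, cl) # ties: lower index -> milder
  names_by_rank <- if (length(cl) == 2) c("mild", "severe") else
    c("mild", sprintf("intermediate-%d", seq_len(length(cl) - 2)), "severe")
  cohort_map <- setNames(names_by_rank, cl[ord])
  out <- assignment
  out$cohort <- unname(cohort_map[as.character(out$cluster)])
  structure(out, class = class(assignment),
            centroids = attr(assignment, "centroids"),
            inertia = attr(assignment, "inertia"),
            panel = panel, scale = attr(assignment, "scale"),
            cohort_names = cohort_map)
}
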