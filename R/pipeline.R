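#' Run the full sendotype discovery pipeline
#'
#' Orchestrates the discovery stages in order: completeness QC, median
#' imputation, bootstrap-PCA ranking, silhouette-constrained forward panel
#' selection, k-means clustering at the chosen k, cohort naming, Welch
#' differential expression, clinical contrasts, renal-trajectory regressions,
#' and (when gene sets are supplied) hypergeometric over-representation of
#' the significant proteins against the assayed background. All randomness
#' flows from `seed`, expanded into fixed per-stage seeds that are recorded
#' in the manifest. When `out_dir` is given, every result table is written as
#' CSV alongside a JSON summary and a run manifest.
#'
#' @param npx An NPX tibble (pre-QC).
#' @param clinical A clinical tibble.
#' @param senescence Character vector of senescence-labelled symbols.
#' @param gene_sets Optional gene-set tibble from [read_gmt()].
#' @param qc_min_fraction Completeness threshold for [qc_filter_proteins()].
#' @param n_bootstraps Bootstrap resamples for the ranking.
#' @param k_range,threshold Panel-selection controls.
#' @param alpha Significance threshold for the ORA query.
#' @param out_dir Optional output directory for the report bundle.
#' @param seed Root integer seed.
#' @return A list of class `sendotype_run`: `npx` (post-QC, imputed),
#'   `ranked`, `panel`, `assignment`, `de`, `clinical_contrasts`,
#'   `trajectories` (eGFR and creatinine), `ora` (or `NULL`), `summary`
#'   (plain list), `manifest`.
#' @export
run_discovery <- function(npx, clinical, senescence, gene_sets = NULL,
                          qc_min_fraction = 0.80, n_bootstraps = 500,
                          k_range = 2:10, threshold = 0.5, alpha = 0.05,
                          out_dir = NULL, seed = 1) {
  seed <- as.integer(seed)
  stage_seed <- function(i) (seed * 131L + i * 7919L) %% .Machine$integer.max
  clinical <- validate_clinical(clinical)

  npx <- as_npx(npx)
  shared <- intersect(npx_patients(npx), clinical$patient_id)
  if (length(shared) < nrow(npx)) {
    abort("Every NPX patient must appear in the clinical table.")
  }
  qc <- qc_filter_proteins(npx, min_fraction = qc_min_fraction, verbose = TRUE)
  complete <- impute_missing(qc)
  severity <- clinical$severity[match(npx_patients(complete), clinical$patient_id)]

  ranked <- bootstrap_rank(complete, labels = severity, senescence = senescence,
                           n_bootstraps = n_bootstraps, seed = stage_seed(1L))
  panel <- forward_panel_selection(ranked, complete, k_range = k_range,
                                   threshold = threshold, seed = stage_seed(2L))
  assignment <- cluster_kmeans(complete, panel = panel$panel, k = panel$chosen_k,
                               seed = stage_seed(3L))
  assignment <- name_cohorts(assignment, complete)

  de <- de_table(complete, assignment, senescence = senescence)
  contrasts <- cohort_clinical_compare(clinical, assignment)
  traj <- bind_rows(
    trajectory_regression(complete, clinical, panel$panel, "egfr_followup"),
    trajectory_regression(complete, clinical, panel$panel, "creatinine_followup")
  )
  enrich <- NULL
  if (!is.null(gene_sets)) {
    query <- de_to_query(de, alpha = alpha)
    if (length(intersect(query, npx_proteins(complete))) > 0) {
      enrich <- ora(query, gene_sets, universe = npx_proteins(complete))
    } else {
      message("No significant proteins at alpha = ", alpha, "; ORA skipped.")
    }
  }

  cohort_sizes <- table(assignment$cohort)
  summary <- list(
    n_patients = nrow(complete),
    n_proteins_prefilter = length(npx_proteins(npx)),
    n_proteins_postqc = length(npx_proteins(qc)),
    panel = panel$panel,
    panel_size = length(panel$panel),
    chosen_k = panel$chosen_k,
    cohort_sizes = as.list(cohort_sizes),
    n_de_significant = sum(de$adj_p < alpha),
    top_de = head(de$protein_id, 10),
    seed = seed
  )
  manifest <- list(
    package = "sendotyper",
    version = as.character(utils::packageVersion("sendotyper")),
    seed = seed,
    stage_seeds = list(ranking = stage_seed(1L), panel = stage_seed(2L),
                       kmeans = stage_seed(3L)),
    inputs = list(
      npx_dim = dim(npx_matrix(npx)),
      n_clinical = nrow(clinical),
      n_senescence_labels = length(senescence),
      n_gene_sets = if (is.null(gene_sets)) 0L else nrow(gene_sets)
    ),
    parameters = list(qc_min_fraction = qc_min_fraction,
                      n_bootstraps = n_bootstraps, k_range = range(k_range),
                      threshold = threshold, alpha = alpha)
  )
  run <- structure(list(npx = complete, ranked = ranked, panel = panel,
                        assignment = assignment, de = de,
                        clinical_contrasts = contrasts, trajectories = traj,
                        ora = enrich, summary = summary, manifest = manifest),
                   class = "sendotype_run")
  if (!is.null(out_dir)) write_run_bundle(run, out_dir)
  run
}

#' Write a discovery run as a CSV/JSON report bundle
#'
#' @param run A `sendotype_run`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run_bundle <- function(run, out_dir) {
  stopifnot(inherits(run, "sendotype_run"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(run$ranked, file.path(out_dir, "ranked_features.csv"))
  readr::write_csv(run$panel$step_trace, file.path(out_dir, "panel_step_trace.csv"))
  readr::write_csv(run$panel$criteria, file.path(out_dir, "cluster_criteria.csv"))
  readr::write_csv(as_tibble(run$assignment), file.path(out_dir, "cluster_assignment.csv"))
  readr::write_csv(run$de, file.path(out_dir, "differential_expression.csv"))
  readr::write_csv(volcano_data(run$de), file.path(out_dir, "volcano.csv"))
  readr::write_csv(heatmap_data(run$de, run$npx, run$assignment),
                   file.path(out_dir, "heatmap_top25.csv"))
  readr::write_csv(run$clinical_contrasts, file.path(out_dir, "clinical_contrasts.csv"))
  readr::write_csv(run$trajectories, file.path(out_dir, "trajectory_regressions.csv"))
  if (!is.null(run$ora)) readr::write_csv(run$ora, file.path(out_dir, "ora.csv"))
  jsonlite::write_json(run$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.sendotype_run <- function(x, ...) {
  s <- x$summary
  cat("Sendotype discovery run\n")
  cat(sprintf("  patients: %d | proteins: %d -> %d after QC\n",
              s$n_patients, s$n_proteins_prefilter, s$n_proteins_postqc))
  cat(sprintf("  panel: %d proteins, k = %d (cohorts: %s)\n", s$panel_size,
              s$chosen_k, paste(sprintf("%s=%d", names(s$cohort_sizes),
                                        unlist(s$cohort_sizes)), collapse = ", ")))
  cat(sprintf("  DE hits (BH < 0.05): %d | top: %s\n", s$n_de_significant,
              paste(head(s$top_de, 4), collapse = ", ")))
  invisible(x)
}
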