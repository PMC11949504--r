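#' Specification of a synthetic CKD proteomics cohort
#'
#' The generator plants two latent patient endotypes ("mild-like" vs
#' "severe-like") separated along a subset of informative proteins, on top of
#' heterogeneous per-protein NPX baselines, and couples renal clinical
#' follow-ups inversely to the informative-protein signal. Defaults emulate a
#' 79-patient, 535-protein Olink-style study with a 16-protein planted panel.
#'
#' @param n_patients,n_proteins Cohort dimensions.
#' @param n_informative Number of proteins shifted between endotypes.
#' @param effect_size Mean NPX shift of informative proteins in the
#'   severe-like endotype (log2 units).
#' @param noise_sd Within-endotype NPX standard deviation.
#' @param missing_rate Uniform per-cell missingness probability.
#' @param mixture_weight Proportion of patients in the severe-like endotype.
#' @param trajectory_slope Coupling of mean informative NPX to
#'   log2(follow-up eGFR); positive values give the inverse NPX-eGFR relation.
#' @param sigma_traj Residual SD of log2(follow-up eGFR) around the coupling.
#' @param n_high_missing Number of (non-informative) proteins given heavy
#'   missingness so the completeness QC has something to drop.
#' @param high_missing_range Range of missing fractions for those proteins;
#'   drawn per protein, always above the 20% QC cut.
#' @param senescent_frac_informative Fraction of informative proteins carrying
#'   the senescence label (default 13/16, the composition of the panel the
#'   method is designed to recover).
#' @param senescent_frac_background Senescence-label rate among the remaining
#'   proteins (inflammation/cardiovascular panels are senescence-rich).
#' @param seed Integer seed; every draw flows from it.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = 79, n_proteins = 535, n_informative = 16,
                        effect_size = 2.7, noise_sd = 1, missing_rate = 0.03,
                        mixture_weight = 0.5, trajectory_slope = 0.4,
                        sigma_traj = 0.1, n_high_missing = 0,
                        high_missing_range = c(0.25, 0.45),
                        senescent_frac_informative = 13 / 16,
                        senescent_frac_background = 0.55,
                        seed = 20180101) {
  spec <- list(
    n_patients = n_patients, n_proteins = n_proteins,
    n_informative = n_informative, effect_size = effect_size,
    noise_sd = noise_sd, missing_rate = missing_rate,
    mixture_weight = mixture_weight, trajectory_slope = trajectory_slope,
    sigma_traj = sigma_traj, n_high_missing = n_high_missing,
    high_missing_range = high_missing_range,
    senescent_frac_informative = senescent_frac_informative,
    senescent_frac_background = senescent_frac_background,
    seed = as.integer(seed)
  )
  if (spec$n_informative < 1 || spec$n_informative > spec$n_proteins) {
    abort("n_informative must be in [1, n_proteins].")
  }
  if (spec$effect_size < 0) abort("effect_size must be non-negative.")
  if (spec$noise_sd <= 0) abort("noise_sd must be positive.")
  if (spec$mixture_weight <= 0 || spec$mixture_weight >= 1) {
    abort("mixture_weight must lie strictly between 0 and 1.")
  }
  if (spec$missing_rate < 0 || spec$missing_rate >= 1) abort("missing_rate must be in [0, 1).")
  if (spec$n_high_missing > spec$n_proteins - spec$n_informative) {
    abort("n_high_missing exceeds the number of non-informative proteins.")
  }
  structure(spec, class = "cohort_spec")
}

# Inverse of the MDRD estimating equation: creatinine (umol/L) giving the
# target eGFR at the patient's age/sex (non-black form).
creatinine_from_egfr <- function(egfr, age, female, constant = 175) {
  base <- constant * age^(-0.203) * ifelse(female, 0.742, 1)
  88.4 * (egfr / base)^(-1 / 1.154)
}

#' Generate a synthetic two-endotype cohort
#'
#' Draws the NPX matrix, clinical table, senescence label list, and the
#' ground truth behind them from a [cohort_spec()]. Informative proteins are
#' `Normal(mu_p + effect_size, noise_sd)` in the severe-like endotype and
#' `Normal(mu_p, noise_sd)` otherwise, with per-protein baselines
#' `mu_p ~ Normal(4, 1)`. Baseline and follow-up eGFR decrease (on the log2
#' scale, at rate `trajectory_slope`) with the patient's mean informative
#' NPX; creatinine is derived by inverting the MDRD equation; severity groups
#' come from KDIGO staging of baseline eGFR; age runs higher in the
#' severe-like endotype. Fully reproducible from `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `sendotype_cohort` with elements `npx` (NPX
#'   tibble), `clinical` (clinical tibble), `labels` (senescence symbols) and
#'   `truth` (list: `endotype` tibble, `informative`, `senescent`).
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients
  p <- spec$n_proteins
  withr::with_seed(spec$seed, {
    patient_ids <- sprintf("CKD%03d", seq_len(n))
    protein_ids <- sprintf("PROT%04d", seq_len(p))
    informative <- sort(sample(protein_ids, spec$n_informative))
    severe <- rbinom(n, 1, spec$mixture_weight)

    mu <- rnorm(p, mean = 4, sd = 1)
    values <- matrix(rnorm(n * p, sd = spec$noise_sd), n, p,
                     dimnames = list(patient_ids, protein_ids))
    values <- sweep(values, 2, mu, "+")
    inf_idx <- match(informative, protein_ids)
    values[, inf_idx] <- values[, inf_idx] + spec$effect_size * severe

    # truth-level severity signal: mean informative NPX per patient
    s <- rowMeans(values[, inf_idx, drop = FALSE])
    s_c <- s - mean(s)

    # clinical table
    female <- runif(n) < 0.40
    age <- pmin(92, pmax(22, round(rnorm(n, 55, 12) + 8 * severe)))
    log2_egfr_base <- log2(47) - spec$trajectory_slope * s_c + rnorm(n, 0, spec$sigma_traj)
    log2_egfr_fup <- log2(45) - spec$trajectory_slope * s_c + rnorm(n, 0, spec$sigma_traj)
    egfr_base <- 2^log2_egfr_base
    egfr_fup <- 2^log2_egfr_fup
    clinical <- tibble(
      patient_id = patient_ids,
      age = age,
      sex = ifelse(female, "female", "male"),
      weight = round(rnorm(n, 85, 18), 1),
      bmi = round(rnorm(n, 29, 5.5), 1),
      systolic_bp = round(rnorm(n, 142, 18)),
      diastolic_bp = round(rnorm(n, 81, 10)),
      diabetes = runif(n) < (0.10 + 0.25 * severe),
      hypercholesterolaemia = runif(n) < (0.28 + 0.22 * severe),
      cvd = runif(n) < (0.12 + 0.10 * severe),
      cause_of_ckd = sample(
        c("glomerulonephritis", "IgA nephropathy", "polycystic", "hypertensive",
          "unknown"), n, replace = TRUE, prob = c(0.25, 0.2, 0.1, 0.15, 0.3)),
      creatinine_baseline = round(creatinine_from_egfr(egfr_base, age, female), 1),
      creatinine_followup = round(creatinine_from_egfr(egfr_fup, age, female), 1),
      egfr_baseline = round(egfr_base, 1),
      egfr_followup = round(egfr_fup, 1),
      urea = round(pmax(1.5, rnorm(n, 7, 2) + 3 * severe), 1),
      severity = severity_group(kdigo_stage(egfr_base))
    )
    clinical <- validate_clinical(clinical)

    # senescence labels: most informative proteins plus a senescence-rich
    # background
    n_sen_inf <- round(spec$senescent_frac_informative * spec$n_informative)
    sen_inf <- sort(sample(informative, n_sen_inf))
    background <- setdiff(protein_ids, informative)
    n_sen_bg <- round(spec$senescent_frac_background * length(background))
    sen_bg <- sort(sample(background, n_sen_bg))
    senescent <- sort(c(sen_inf, sen_bg))

    # missingness: uniform noise plus designated heavy-missing proteins
    if (spec$missing_rate > 0) {
      drop_mask <- matrix(runif(n * p) < spec$missing_rate, n, p)
      values[drop_mask] <- NA_real_
    }
    high_missing <- character(0)
    if (spec$n_high_missing > 0) {
      high_missing <- sort(sample(background, spec$n_high_missing))
      for (pr in high_missing) {
        n_miss <- round(runif(1, spec$high_missing_range[1],
                              spec$high_missing_range[2]) * n)
        values[sample(n, n_miss), match(pr, protein_ids)] <- NA_real_
      }
    }

    npx <- dplyr::bind_cols(tibble(patient_id = patient_ids), as_tibble(values))
    structure(list(
      npx = as_npx(npx),
      clinical = clinical,
      labels = senescent,
      truth = list(
        endotype = tibble(
          patient_id = patient_ids,
          endotype = ifelse(severe == 1, "severe-like", "mild-like")
        ),
        informative = informative,
        senescent = senescent,
        high_missing = high_missing
      ),
      spec = spec
    ), class = "sendotype_cohort")
  })
}

#' Generate cell-type-structured synthetic single-cell counts
#'
#' Negative-binomial counts for `n_samples` biopsy-like samples, each
#' contributing `cells_per_type` cells of each of `n_celltypes` cell types.
#' Per-cell library-size factors are log-normal (well over 4-fold spread),
#' per-gene baselines are log-normal, and each cell type modulates every gene
#' by its own log-normal factor. A planted injury signature multiplies
#' `n_de_genes` genes by `2^lfc` in the injured (case) samples. Optionally,
#' the last `n_low_count` case samples are starved (library factors scaled by
#' `low_count_factor`) to exercise low-expression sample removal.
#'
#' @param n_samples Total samples; the first `round(injury_fraction *
#'   n_samples)` are cases.
#' @param n_genes,n_celltypes,cells_per_type Dimensions.
#' @param injury_fraction Fraction of samples in the injured condition.
#' @param n_de_genes,lfc Planted signature size and log2 fold change.
#' @param nb_size Negative-binomial size (inverse dispersion).
#' @param n_low_count,low_count_factor Starved-sample controls.
#' @param seed Integer seed.
#' @return A list of class `sendotype_counts`: `counts` (sparse cells x genes
#'   dgCMatrix), `cells` (tibble: cell_id, sample_id, cell_type, condition),
#'   `genes` (tibble), `truth` (planted DE gene ids, starved sample ids).
#' @export
generate_counts <- function(n_samples = 12, n_genes = 1000, n_celltypes = 3,
                            injury_fraction = 0.5, n_de_genes = 50, lfc = 2,
                            cells_per_type = 40, nb_size = 10,
                            n_low_count = 0, low_count_factor = 0.002,
                            seed = 20180101) {
  if (n_celltypes < 1) abort("n_celltypes must be at least 1.")
  n_case <- round(injury_fraction * n_samples)
  if (n_case < 1 || n_case >= n_samples) abort("injury_fraction leaves an empty condition.")
  if (n_low_count >= n_case) abort("n_low_count must be smaller than the number of cases.")
  if (n_de_genes > n_genes) abort("n_de_genes cannot exceed n_genes.")
  withr::with_seed(as.integer(seed), {
    sample_ids <- sprintf("S%02d", seq_len(n_samples))
    condition <- setNames(rep(c("case", "control"), c(n_case, n_samples - n_case)),
                          sample_ids)
    celltypes <- c("immune", "endothelial", "epithelial",
                   sprintf("celltype%d", seq_len(max(0, n_celltypes - 3))))[seq_len(n_celltypes)]
    gene_ids <- sprintf("GENE%04d", seq_len(n_genes))
    de_genes <- if (n_de_genes > 0) sort(sample(gene_ids, n_de_genes)) else character(0)
    starved <- if (n_low_count > 0) sample_ids[seq(n_case - n_low_count + 1, n_case)] else character(0)

    base_mu <- exp(rnorm(n_genes, log(0.5), 1.2))
    ct_factor <- matrix(exp(rnorm(n_celltypes * n_genes, 0, 0.5)),
                        n_celltypes, n_genes, dimnames = list(celltypes, NULL))
    de_mult <- rep(1, n_genes)
    de_mult[match(de_genes, gene_ids)] <- 2^lfc

    cells <- tidyr::expand_grid(sample_id = sample_ids, cell_type = celltypes,
                                rep = seq_len(cells_per_type))
    cells$cell_id <- sprintf("CELL%05d", seq_len(nrow(cells)))
    cells$condition <- condition[cells$sample_id]
    size_factor <- exp(rnorm(nrow(cells), 0, 0.5))
    size_factor[cells$sample_id %in% starved] <-
      size_factor[cells$sample_id %in% starved] * low_count_factor

    mu <- ct_factor[cells$cell_type, , drop = FALSE] * size_factor
    case_cell <- cells$condition == "case"
    mu <- sweep(mu, 2, base_mu, "*")
    mu[case_cell, ] <- sweep(mu[case_cell, , drop = FALSE], 2, de_mult, "*")
    counts <- matrix(rnbinom(length(mu), mu = as.vector(mu), size = nb_size),
                     nrow(cells), n_genes,
                     dimnames = list(cells$cell_id, gene_ids))
    structure(list(
      counts = methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
      cells = cells[c("cell_id", "sample_id", "cell_type", "condition")],
      genes = tibble(gene_id = gene_ids),
      truth = list(de_genes = de_genes, starved_samples = starved)
    ), class = "sendotype_counts")
  })
}

#' Write / read a single-cell count bundle (MatrixMarket + TSV)
#'
#' `write_counts_mtx()` writes `matrix.mtx` (cells x genes), `genes.tsv`,
#' `barcodes.tsv` and `annotations.tsv` into `dir`; `read_counts_mtx()`
#' reassembles the `sendotype_counts` object (without generator truth).
#'
#' @param x A `sendotype_counts` object.
#' @param dir Directory (created if absent).
#' @return `write_counts_mtx()` the directory, invisibly;
#'   `read_counts_mtx()` a `sendotype_counts` list.
#' @export
write_counts_mtx <- function(x, dir) {
  stopifnot(inherits(x, "sendotype_counts"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(x$counts, file.path(dir, "matrix.mtx"))
  readr::write_tsv(x$genes, file.path(dir, "genes.tsv"), col_names = FALSE)
  readr::write_tsv(tibble(cell_id = rownames(x$counts)),
                   file.path(dir, "barcodes.tsv"), col_names = FALSE)
  readr::write_tsv(x$cells, file.path(dir, "annotations.tsv"))
  invisible(dir)
}

#' @rdname write_counts_mtx
#' @export
read_counts_mtx <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  genes <- readr::read_tsv(file.path(dir, "genes.tsv"), col_names = "gene_id",
                           show_col_types = FALSE, progress = FALSE)
  barcodes <- readr::read_tsv(file.path(dir, "barcodes.tsv"), col_names = "cell_id",
                              show_col_types = FALSE, progress = FALSE)
  cells <- readr::read_tsv(file.path(dir, "annotations.tsv"),
                           show_col_types = FALSE, progress = FALSE)
  dimnames(counts) <- list(barcodes$cell_id, genes$gene_id)
  structure(list(counts = counts, cells = cells, genes = genes,
                 truth = NULL), class = "sendotype_counts")
}
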