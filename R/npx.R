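#' NPX matrices as tibbles
#'
#' Throughout the package an NPX matrix (Normalized Protein eXpression,
#' log2-scale relative abundance) is a wide tibble: one row per patient, a
#' `patient_id` character column first, then one numeric column per protein.
#' `NA` marks a missing assay value. `as_npx()` validates a data frame into
#' this shape; `npx_matrix()` extracts the numeric matrix (patients x
#' proteins, row names = patient ids) that the numerical stages consume.
#'
#' @param x A data frame with a `patient_id` column and numeric protein
#'   columns.
#' @return `as_npx()` returns the validated tibble; `npx_matrix()` a numeric
#'   matrix; `npx_proteins()` / `npx_patients()` character vectors of ids.
#' @examples
#' npx <- as_npx(data.frame(patient_id = c("P1", "P2"), TNFR1 = c(4.2, 5.1)))
#' npx_matrix(npx)
#' @export
as_npx <- function(x) {
  stopifnot(is.data.frame(x))
  if (!"patient_id" %in% names(x)) {
    abort("NPX table must have a 'patient_id' column.")
  }
  x <- as_tibble(x)
  x$patient_id <- as.character(x$patient_id)
  dup_p <- unique(x$patient_id[duplicated(x$patient_id)])
  if (length(dup_p) > 0) {
    abort(paste0("Duplicate patient ids: ", paste(dup_p, collapse = ", ")))
  }
  prot <- setdiff(names(x), "patient_id")
  dup_g <- unique(prot[duplicated(prot)])
  if (length(dup_g) > 0) {
    abort(paste0("Duplicate protein ids: ", paste(dup_g, collapse = ", ")))
  }
  bad <- prot[!vapply(x[prot], is.numeric, logical(1))]
  if (length(bad) > 0) {
    abort(paste0("Non-numeric protein columns: ", paste(bad, collapse = ", ")))
  }
  nonfinite <- vapply(x[prot], function(v) any(!is.finite(v) & !is.na(v)), logical(1))
  if (any(nonfinite)) {
    abort(paste0(
      "Non-finite NPX values in: ",
      paste(prot[nonfinite], collapse = ", ")
    ))
  }
  x[c("patient_id", prot)]
}

#' @rdname as_npx
#' @export
npx_matrix <- function(x) {
  x <- as_npx(x)
  m <- as.matrix(x[setdiff(names(x), "patient_id")])
  rownames(m) <- x$patient_id
  m
}

#' @rdname as_npx
#' @export
npx_proteins <- function(x) setdiff(names(as_npx(x)), "patient_id")

#' @rdname as_npx
#' @export
npx_patients <- function(x) as_npx(x)$patient_id

# Sniff the field delimiter of a delimited text file (tab beats comma).
guess_delim <- function(path) {
  l1 <- readLines(path, n = 1L)
  if (grepl("\t", l1)) "\t" else if (grepl(",", l1)) "," else if (grepl(";", l1)) ";" else "\t"
}

#' Read and write NPX matrices
#'
#' Reads a delimited text file of NPX values into the package's wide-tibble
#' representation, regardless of whether the file stores patients as rows or
#' proteins as rows. Empty cells and `NA` denote missing values. Non-numeric
#' cells and duplicated ids are hard errors (with coordinates / offending
#' ids), since silent coercion would corrupt downstream statistics.
#'
#' @param path Path to a CSV/TSV file whose first column (or row) holds ids.
#' @param orientation `"patients_as_rows"` (default) if rows are patients, or
#'   `"proteins_as_rows"` if the file is transposed.
#' @param delim Field delimiter; `NULL` (default) sniffs tab/comma/semicolon.
#' @return An NPX tibble (see [as_npx()]) in patients-as-rows orientation.
#' @export
read_npx <- function(path, orientation = c("patients_as_rows", "proteins_as_rows"),
                     delim = NULL) {
  orientation <- arg_match(orientation)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  if (is.null(delim)) delim <- guess_delim(path)
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           na = character(), progress = FALSE,
                           name_repair = "minimal")
  ids <- as.character(raw[[1]])
  cells <- as.matrix(raw[-1])
  cells[cells == "" | toupper(cells) == "NA"] <- NA_character_
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which(is.na(num) & !is.na(cells), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    b <- bad[1, ]
    abort(sprintf(
      "Non-numeric cell '%s' at data row %d, column '%s'.",
      cells[b[1], b[2]], b[1], colnames(cells)[b[2]]
    ))
  }
  dimnames(num) <- list(ids, colnames(cells))
  if (orientation == "proteins_as_rows") num <- t(num)
  dup <- unique(rownames(num)[duplicated(rownames(num))])
  if (length(dup) > 0) abort(paste0("Duplicate patient ids: ", paste(dup, collapse = ", ")))
  dupc <- unique(colnames(num)[duplicated(colnames(num))])
  if (length(dupc) > 0) abort(paste0("Duplicate protein ids: ", paste(dupc, collapse = ", ")))
  out <- as_tibble(num)
  out <- dplyr::bind_cols(tibble(patient_id = rownames(num)), out)
  as_npx(out)
}

#' @rdname read_npx
#' @param x An NPX tibble.
#' @export
write_npx <- function(x, path, delim = "\t") {
  x <- as_npx(x)
  readr::write_delim(x, path, delim = delim, na = "NA")
  invisible(path)
}

#' Quality-control filter on protein completeness
#'
#' Retains exactly the proteins whose non-missing fraction across patients is
#' strictly greater than `min_fraction` (default 0.80, i.e. a protein must be
#' recorded in *over* 80% of patients to survive). Patients are never dropped
#' and retained values are never altered. Idempotent.
#'
#' @param x An NPX tibble.
#' @param min_fraction Completeness threshold in (0, 1]; proteins at exactly
#'   the threshold are dropped.
#' @param verbose Log retained/dropped counts via `message()`.
#' @return The filtered NPX tibble, with attributes `qc_dropped` (dropped
#'   protein ids) and `qc_retained` (count).
#' @export
qc_filter_proteins <- function(x, min_fraction = 0.80, verbose = FALSE) {
  x <- as_npx(x)
  stopifnot(is.numeric(min_fraction), length(min_fraction) == 1,
            min_fraction > 0, min_fraction <= 1)
  m <- npx_matrix(x)
  frac <- colMeans(!is.na(m))
  keep <- frac > min_fraction
  if (!any(keep)) {
    abort(paste0(
      "QC removed every protein (best completeness ",
      sprintf("%.3f", max(frac)), "); review min_fraction."
    ))
  }
  dropped <- colnames(m)[!keep]
  if (verbose) {
    message(sprintf("QC: retained %d / %d proteins (> %.0f%% complete); dropped %d.",
                    sum(keep), ncol(m), 100 * min_fraction, length(dropped)))
  }
  out <- x[c("patient_id", colnames(m)[keep])]
  attr(out, "qc_dropped") <- dropped
  attr(out, "qc_retained") <- sum(keep)
  out
}

#' Impute missing NPX values
#'
#' Replaces each missing value with the median of the protein's observed
#' values. PCA and k-means require complete data; the per-protein median is
#' robust on log-scale measurements and leaves every observed value untouched.
#'
#' @param x An NPX tibble (post-QC).
#' @param method Imputation method; only `"per_protein_median"` is provided.
#' @return A complete NPX tibble (no `NA`).
#' @export
impute_missing <- function(x, method = "per_protein_median") {
  method <- arg_match(method, "per_protein_median")
  x <- as_npx(x)
  m <- npx_matrix(x)
  all_miss <- colnames(m)[colSums(!is.na(m)) == 0]
  if (length(all_miss) > 0) {
    abort(paste0(
      "Fully missing proteins (run qc_filter_proteins() first): ",
      paste(all_miss, collapse = ", ")
    ))
  }
  med <- apply(m, 2, median, na.rm = TRUE)
  for (j in seq_len(ncol(m))) {
    miss <- is.na(m[, j])
    if (any(miss)) m[miss, j] <- med[j]
  }
  out <- dplyr::bind_cols(tibble(patient_id = x$patient_id), as_tibble(m))
  as_npx(out)
}

#' Read a GMT gene-set collection
#'
#' Broad-dialect GMT: one tab-separated line per set, fields
#' `term<TAB>description<TAB>member1<TAB>member2...`. Lines with fewer than
#' three fields are malformed and raise an error naming the line.
#'
#' @param path Path to a `.gmt` file.
#' @return A tibble with columns `term_id`, `description`, and a `genes`
#'   list-column of unique member symbols.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3)
  if (length(short) > 0) {
    abort(sprintf("Malformed GMT line %d: fewer than 3 tab-separated fields.", short[1]))
  }
  out <- tibble(
    term_id = vapply(parts, `[[`, character(1), 1),
    description = vapply(parts, `[[`, character(1), 2),
    genes = lapply(parts, function(p) unique(p[-(1:2)]))
  )
  dup <- unique(out$term_id[duplicated(out$term_id)])
  if (length(dup) > 0) abort(paste0("Duplicate term ids: ", paste(dup, collapse = ", ")))
  if (any(lengths(out$genes) == 0)) abort("GMT contains an empty gene set.")
  out
}

#' Read a senescence label list
#'
#' One protein/gene symbol per line; blank lines ignored; duplicates are
#' removed with a warning (label membership is a set).
#'
#' @param path Path to a plain-text file.
#' @return A character vector of unique symbols.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  syms <- trimws(readLines(path))
  syms <- syms[nzchar(syms)]
  if (length(syms) == 0) abort("Label file contains no symbols.")
  if (anyDuplicated(syms)) {
    warn(sprintf("%d duplicate label symbols removed.", sum(duplicated(syms))))
    syms <- unique(syms)
  }
  syms
}

clinical_required_cols <- c(
  "patient_id", "age", "sex", "weight", "bmi", "systolic_bp", "diastolic_bp",
  "diabetes", "hypercholesterolaemia", "cvd", "cause_of_ckd",
  "creatinine_baseline", "creatinine_followup",
  "egfr_baseline", "egfr_followup", "urea", "severity"
)

#' Read and validate a clinical table
#'
#' One row per patient with demographics (age in years, sex, weight kg, BMI,
#' blood pressures mmHg), comorbidity flags, cause of CKD, baseline and
#' 1-year follow-up creatinine (umol/L) and eGFR (mL/min/1.73 m^2), urea
#' (mmol/L), and a `severity` group (`mild`/`moderate`/`severe`).
#'
#' @param path Path to a CSV/TSV file.
#' @param delim Field delimiter; `NULL` sniffs it.
#' @return A validated clinical tibble.
#' @export
read_clinical <- function(path, delim = NULL) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  if (is.null(delim)) delim <- guess_delim(path)
  x <- readr::read_delim(path, delim = delim, show_col_types = FALSE, progress = FALSE)
  validate_clinical(x)
}

#' @rdname read_clinical
#' @param x A data frame to validate in place of reading a file.
#' @export
validate_clinical <- function(x) {
  x <- as_tibble(x)
  missing_cols <- setdiff(clinical_required_cols, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("Clinical table missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  x$patient_id <- as.character(x$patient_id)
  if (anyDuplicated(x$patient_id)) abort("Duplicate patient ids in clinical table.")
  if (any(x$age <= 0, na.rm = TRUE)) abort("Ages must be positive.")
  if (any(x$creatinine_baseline <= 0, na.rm = TRUE)) abort("Creatinine must be positive.")
  if (any(is.na(x$severity))) abort("severity must be present for every patient.")
  bad_sev <- setdiff(unique(as.character(x$severity)), c("mild", "moderate", "severe"))
  if (length(bad_sev) > 0) {
    abort(paste0("Unknown severity levels: ", paste(bad_sev, collapse = ", ")))
  }
  x$severity <- factor(as.character(x$severity), levels = c("mild", "moderate", "severe"))
  x
}
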