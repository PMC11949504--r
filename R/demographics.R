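#' Published baseline demographics of a three-group CKD cohort
#'
#' Reference demographic tables for a 79-patient CKD cohort stratified into
#' mild (n = 40), moderate (n = 23) and severe (n = 16) severity groups, as
#' such studies print them: continuous variables as per-group n/mean/SD
#' (`type = "summary"`; age years, creatinine umol/L, GFR mL/min/1.73 m^2,
#' weight kg, BMI, blood pressures mmHg) and categorical variables as
#' per-group counts (`type = "counts"`; gender, diabetes,
#' hypercholesterolaemia, CVD). These feed [anova_from_summary()] and
#' [chi_squared_test()] and anchor the package's golden tests: the recomputed
#' p-values are age .014, weight .048 (printed; recomputes to .046 from the
#' rounded summaries), creatinine and GFR < .001, gender .365, diabetes .012,
#' hypercholesterolaemia .095, CVD .517.
#'
#' @param type `"summary"` (continuous) or `"counts"` (categorical).
#' @return A tibble.
#' @export
ckd_demographics <- function(type = c("summary", "counts")) {
  type <- arg_match(type)
  path <- system.file("extdata",
                      paste0("ckd_demographics_", type, ".tsv"),
                      package = "sendotyper", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Contingency matrix for one categorical demographic variable
#'
#' @param variable One of `"gender"`, `"diabetes"`,
#'   `"hypercholesterolaemia"`, `"cvd"`.
#' @return A levels x severity-group count matrix.
#' @export
demographic_counts_matrix <- function(variable) {
  counts <- ckd_demographics("counts")
  counts <- counts[counts$variable == variable, ]
  if (nrow(counts) == 0) abort(paste0("Unknown demographic variable: ", variable))
  m <- as.matrix(counts[c("mild", "moderate", "severe")])
  rownames(m) <- counts$level
  m
}
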