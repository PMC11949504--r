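#' One-way ANOVA from group summary statistics
#'
#' Recovers the exact one-way ANOVA F test from per-group `n`, `mean`, `sd`
#' (the form demographic tables print): `SSB = sum n_i (m_i - m)^2`,
#' `SSW = sum (n_i - 1) s_i^2`, `F = (SSB/(k-1)) / (SSW/(N-k))`. On exact
#' summaries this is algebraically identical to raw-data ANOVA.
#'
#' @param groups A data frame with columns `n`, `mean`, `sd` (one row per
#'   group; `n >= 2` each).
#' @return A one-row tibble: `f_stat`, `df1`, `df2`, `p_value`.
#' @export
anova_from_summary <- function(groups) {
  stopifnot(is.data.frame(groups), all(c("n", "mean", "sd") %in% names(groups)))
  if (nrow(groups) < 2) abort("ANOVA needs at least two groups.")
  if (any(groups$n < 2)) abort("Each group needs n >= 2.")
  n <- groups$n; m <- groups$mean; s <- groups$sd
  N <- sum(n); k <- length(n)
  gm <- sum(n * m) / N
  ssb <- sum(n * (m - gm)^2)
  ssw <- sum((n - 1) * s^2)
  if (ssw == 0) {
    if (ssb == 0) return(tibble(f_stat = 0, df1 = k - 1, df2 = N - k, p_value = 1))
    return(tibble(f_stat = Inf, df1 = k - 1, df2 = N - k, p_value = 0))
  }
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  tibble(f_stat = f, df1 = k - 1, df2 = N - k,
         p_value = pf(f, k - 1, N - k, lower.tail = FALSE))
}

#' Pearson chi-squared test of a contingency table
#'
#' [stats::chisq.test()] without continuity correction (the convention that
#' reproduces published three-group demographic p-values), returned tidily.
#'
#' @param counts An r x c matrix or data frame of counts.
#' @return A one-row tibble: `statistic`, `df`, `p_value`.
#' @export
chi_squared_test <- function(counts) {
  counts <- as.matrix(counts)
  if (length(counts) == 0 || sum(counts) == 0) abort("Empty contingency table.")
  fit <- suppressWarnings(chisq.test(counts, correct = FALSE))
  tibble(statistic = unname(fit$statistic), df = unname(fit$parameter),
         p_value = fit$p.value)
}

#' MDRD estimated glomerular filtration rate
#'
#' The IDMS-traceable re-expressed MDRD equation:
#' `eGFR = 175 * (creatinine/88.4)^-1.154 * age^-0.203 * 0.742[female] *
#' 1.212[black]`, with creatinine in umol/L (divided by 88.4 to mg/dL) and
#' eGFR in mL/min/1.73 m^2. The classic constant 186 is available through
#' `constant`.
#'
#' @param creatinine_umol_l Serum creatinine, umol/L (> 0).
#' @param age_years Age in years (> 0).
#' @param sex `"female"` or `"male"` (vectorised).
#' @param black Logical; Black-race coefficient.
#' @param constant 175 (IDMS-traceable, default) or 186.
#' @return eGFR in mL/min/1.73 m^2.
#' @export
mdrd_egfr <- function(creatinine_umol_l, age_years, sex, black = FALSE,
                      constant = 175) {
  if (any(creatinine_umol_l <= 0, na.rm = TRUE)) abort("Creatinine must be positive.")
  if (any(age_years <= 0, na.rm = TRUE)) abort("Age must be positive.")
  sex <- tolower(as.character(sex))
  if (!all(sex %in% c("female", "male"))) abort("sex must be 'female' or 'male'.")
  constant * (creatinine_umol_l / 88.4)^(-1.154) * age_years^(-0.203) *
    ifelse(sex == "female", 0.742, 1) * ifelse(black, 1.212, 1)
}

#' KDIGO CKD stage from eGFR
#'
#' G1 >= 90; G2 60-89; G3a 45-59; G3b 30-44; G4 15-29; G5 < 15 (ranges are
#' `[lower, upper + 1)` half-open bins, mL/min/1.73 m^2).
#'
#' @param egfr eGFR values.
#' @return A factor with levels G1, G2, G3a, G3b, G4, G5.
#' @export
kdigo_stage <- function(egfr) {
  if (any(egfr < 0, na.rm = TRUE)) abort("eGFR must be non-negative.")
  cut(egfr, breaks = c(-Inf, 15, 30, 45, 60, 90, Inf),
      labels = c("G5", "G4", "G3b", "G3a", "G2", "G1"),
      right = FALSE) |>
    factor(levels = c("G1", "G2", "G3a", "G3b", "G4", "G5"))
}

#' Severity group from KDIGO stage
#'
#' Mild: stages up to 3a; moderate: 3b; severe: 4 and 5.
#'
#' @param stage A factor/character of KDIGO stages.
#' @return A factor with levels mild, moderate, severe.
#' @export
severity_group <- function(stage) {
  stage <- as.character(stage)
  bad <- setdiff(unique(stage), c("G1", "G2", "G3a", "G3b", "G4", "G5", NA))
  if (length(bad) > 0) abort(paste0("Unknown KDIGO stages: ", paste(bad, collapse = ", ")))
  out <- ifelse(stage %in% c("G1", "G2", "G3a"), "mild",
                ifelse(stage == "G3b", "moderate", "severe"))
  factor(out, levels = c("mild", "moderate", "severe"))
}

#' Renal-trajectory regressions of panel proteins
#'
#' Ordinary least squares of NPX (response) on log2 of a follow-up renal
#' outcome (regressor), one model per protein — the orientation of the
#' trajectory figures: protein expression on the y-axis against
#' log2(follow-up eGFR or creatinine) on the x-axis. A negative slope against
#' eGFR means the protein rises as renal function declines.
#'
#' @param x A complete NPX tibble.
#' @param clinical A clinical tibble sharing `patient_id`.
#' @param proteins Protein ids to fit (e.g. the selected panel).
#' @param outcome `"egfr_followup"` or `"creatinine_followup"` (must be
#'   positive; log2 is applied internally).
#' @return A tibble with one row per protein: `protein_id`, `outcome`,
#'   `slope`, `intercept`, `r_squared`, `p_value` (two-sided slope test),
#'   `n`.
#' @export
trajectory_regression <- function(x, clinical, proteins = NULL,
                                  outcome = c("egfr_followup", "creatinine_followup")) {
  outcome <- arg_match(outcome)
  if (is.null(proteins)) proteins <- npx_proteins(x)
  m <- npx_matrix(x)
  shared <- intersect(rownames(m), clinical$patient_id)
  if (length(shared) < 3) abort("Need >= 3 patients shared between NPX and clinical tables.")
  out_val <- clinical[[outcome]][match(shared, clinical$patient_id)]
  if (any(out_val <= 0, na.rm = TRUE)) abort(paste0(outcome, " must be positive for log2."))
  reg <- log2(out_val)
  if (sd(reg, na.rm = TRUE) == 0) abort("Outcome is constant; regression undefined.")
  purrr::map_dfr(proteins, function(pr) {
    fit <- lm(m[shared, pr] ~ reg)
    sm <- summary(fit)
    tibble(protein_id = pr, outcome = outcome,
           slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
           r_squared = sm$r.squared,
           p_value = sm$coefficients[2, 4],
           n = length(shared))
  })
}

#' Clinical contrasts between sendotype cohorts
#'
#' Welch-tests age, urea, baseline and follow-up eGFR and creatinine between
#' the severe and mild cohorts, reporting group means and the direction of
#' the difference.
#'
#' @param clinical A clinical tibble.
#' @param assignment A named `cluster_assignment` (with `cohort` column).
#' @param variables Clinical columns to contrast.
#' @return A tibble: `variable`, `mean_mild`, `mean_severe`, `direction`
#'   (`"higher_in_severe"` / `"lower_in_severe"` / `"equal"`), `t_stat`,
#'   `p_value`.
#' @export
cohort_clinical_compare <- function(clinical, assignment,
                                    variables = c("age", "urea", "egfr_baseline",
                                                  "egfr_followup", "creatinine_baseline",
                                                  "creatinine_followup")) {
  stopifnot(all(c("patient_id", "cohort") %in% names(assignment)))
  joined <- left_join(assignment[c("patient_id", "cohort")], clinical, by = "patient_id")
  missing_vars <- setdiff(variables, names(joined))
  if (length(missing_vars) > 0) {
    abort(paste0("Clinical table lacks: ", paste(missing_vars, collapse = ", ")))
  }
  purrr::map_dfr(variables, function(v) {
    sev <- joined[[v]][joined$cohort == "severe"]
    mil <- joined[[v]][joined$cohort == "mild"]
    wt <- welch_t_test(sev, mil)
    d <- mean(sev, na.rm = TRUE) - mean(mil, na.rm = TRUE)
    tibble(variable = v, mean_mild = mean(mil, na.rm = TRUE),
           mean_severe = mean(sev, na.rm = TRUE),
           direction = if (d > 0) "higher_in_severe" else if (d < 0) "lower_in_severe" else "equal",
           t_stat = wt$t_stat, p_value = wt$p_value)
  })
}

#' Long-format clinical export for violin plots
#'
#' @inheritParams cohort_clinical_compare
#' @return A long tibble: `patient_id`, `cohort`, `variable`, `value`.
#' @export
clinical_long <- function(clinical, assignment,
                          variables = c("age", "urea", "egfr_baseline",
                                        "egfr_followup", "creatinine_baseline",
                                        "creatinine_followup")) {
  left_join(assignment[c("patient_id", "cohort")], clinical, by = "patient_id") %>%
    select(all_of(c("patient_id", "cohort", variables))) %>%
    tidyr::pivot_longer(all_of(variables), names_to = "variable", values_to = "value")
}
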