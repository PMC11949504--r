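# sendotyper

Senescence-endotype ("sendotype") discovery from plasma proteomics, for
researchers studying heterogeneity in chronic kidney disease (CKD) cohorts
profiled with Olink-style panels.

CKD patients at the same clinical stage differ widely in trajectory, and the
secretome of senescent cells is a candidate driver. `sendotyper` asks: **is
there a small panel of senescence-associated plasma proteins that splits a
cohort into clinically distinct subgroups?** It implements the full
discovery pipeline as tidyverse-style R functions (data frames in, tibbles
out), plus a synthetic-cohort generator so every stage is testable without
patient data.

## The method

Given an NPX matrix **X** (patients × proteins, log2 scale), clinical
severity groups, and a senescence label set *S*:

1. **QC**: keep proteins with non-missing fraction > 0.8; median-impute the
   rest.
2. **Ranking**: for b = 1..500 bootstrap resamples of patients, fit a PCA of
   the z-scored matrix, select the component whose scores maximise the
   one-way ANOVA F across severity groups, sign-align its loading vector
   w⁽ᵇ⁾ to the full-data fit, and rank proteins by median_b |w_j⁽ᵇ⁾|.
3. **Panel selection**: grow a panel along the ranking; retain the longest
   prefix with best-over-k mean silhouette ≥ 0.5 for k ∈ {2..10}; choose k
   by mean silhouette, with Calinski–Harabasz and within-cluster SS reported
   for validation.
4. **Characterisation**: k-means cohorts (higher mean panel NPX → severe);
   per-protein Welch t tests with Benjamini–Hochberg correction (NPX mean
   difference *is* the log2 fold change); clinical contrasts; OLS of NPX on
   log2(follow-up eGFR/creatinine), with eGFR from the MDRD equation
   `175 · (crea/88.4)^-1.154 · age^-0.203 · 0.742[female]`; hypergeometric
   over-representation of significant proteins against the assayed
   background.
5. **Validation on single-cell counts**: per-(sample, cell type) pseudobulk
   summation, CPM/TPM, low-expression sample removal, and the same Welch/BH
   engine on log2(TPM + 1).

## Worked example

```r
library(sendotyper)

cohort <- generate_cohort(cohort_spec())   # 79 patients x 535 proteins,
                                           # 16 planted panel proteins
run <- run_discovery(cohort$npx, cohort$clinical, cohort$labels, seed = 1)
run
#> Sendotype discovery run
#>   patients: 79 | proteins: 535 -> 535 after QC
#>   panel: 16 proteins, k = 2 (cohorts: mild=42, severe=37)
#>   DE hits (BH < 0.05): 16 | top: PROT0322, PROT0488, PROT0261, PROT0187
```

The pipeline recovers the 16 planted proteins at k = 2 and splits the
cohort into a mild and a severe sendotype. The severe cohort has the worse
renal profile, and each panel protein tracks follow-up renal function:

```r
dplyr::filter(run$trajectories, outcome == "egfr_followup") |>
  dplyr::summarise(min_r2 = min(r_squared), max_slope = max(slope))
#> # A tibble: 1 × 2
#>   min_r2 max_slope
#>    <dbl>     <dbl>
#> 1  0.534     -2.04
```

Every panel protein regresses on log2(follow-up eGFR) with R² > 0.5 and a
negative slope: higher senescence-protein expression, lower renal function a
year later. `autoplot()` methods show the ranking, the silhouette-vs-panel
trace, and the volcano; `tidy()`/`glance()` give broom-style summaries;
`write_run_bundle()` exports every table as CSV with a JSON manifest.

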