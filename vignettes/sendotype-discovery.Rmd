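---
title: "Discovering senescence endotypes in CKD plasma proteomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering senescence endotypes in CKD plasma proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Chronic kidney disease (CKD) is clinically staged by estimated glomerular
filtration rate (eGFR), but patients at the same stage can differ widely in
trajectory. Cellular senescence — and the inflammatory secretome of senescent
cells (the SASP) — is a candidate driver of that heterogeneity. `sendotyper`
implements a discovery pipeline for **sendotypes**: patient subgroups defined
by the plasma abundance of senescence-associated proteins rather than by
clinical stage. The inputs are an Olink-style NPX matrix (log2-scale relative
protein abundance, patients × proteins), a clinical table with baseline and
one-year follow-up renal chemistry, and a list of protein symbols labelled as
differentially expressed in senescence models.

The pipeline runs, in order:

1. **Completeness QC** — keep proteins recorded in strictly more than 80% of
   patients.
2. **Median imputation** — PCA and k-means need complete data; remaining
   gaps are filled with the per-protein median.
3. **Bootstrap-PCA ranking** — resample patients with replacement 500 times;
   each time, fit a PCA and keep the component whose scores carry the most
   severity-class variance; rank proteins by the **median absolute loading**
   across bootstraps.
4. **Forward panel selection** — grow a panel along the ranking; keep the
   longest prefix whose best silhouette over k = 2..10 stays ≥ 0.5.
5. **Clustering and naming** — k-means at the silhouette-optimal k; the
   cluster with higher mean panel NPX is the *severe* cohort.
6. **Characterisation** — Welch differential expression with BH correction,
   clinical contrasts, OLS regressions of NPX on log2(follow-up eGFR and
   creatinine), and hypergeometric over-representation of the significant
   proteins against the assayed background.
7. **Transcriptomic validation** — cell-type pseudobulk aggregation of
   single-cell counts, CPM/TPM normalisation, low-expression sample removal,
   and the same Welch/BH engine on log2(TPM + 1).

## A worked run on synthetic data

No patient-level cohort ships with the package; a generator produces cohorts
with the statistical structure the method assumes:

```{r, eval = FALSE}
library(sendotyper)

cohort <- generate_cohort(cohort_spec())   # 79 patients x 535 proteins
run <- run_discovery(cohort$npx, cohort$clinical, cohort$labels, seed = 1)
run
glance(run$panel)
autoplot(run$panel)       # silhouette vs panel size, per k
autoplot(run$de)          # volcano
```

On the default fixture the pipeline selects the 16 planted proteins at
k = 2, 13 of which carry the senescence label, and every panel protein
regresses on log2(follow-up eGFR) with R² above 0.5 and a negative slope —
the configuration the method is designed to detect.

## The model behind the generator

The generator is first-class, tested code: its defaults *are* the study
conditions every recovery experiment assumes.

**Proteins.** Each protein has a baseline `mu_p ~ Normal(4, 1)` NPX —
heterogeneous baselines prevent trivially standardised inputs. A set of
`n_informative` proteins (default 16) is shifted by `effect_size` NPX in the
severe-like endotype; all others are endotype-independent
`Normal(mu_p, noise_sd)`. Patients are severe-like with probability
`mixture_weight` (default 0.5).

**Clinical coupling.** With `s_i` the patient's mean informative NPX,

```
log2(eGFR) = log2(45) − trajectory_slope · (s_i − mean(s)) + Normal(0, sigma_traj)
```

for the follow-up (baseline uses log2(47) and an independent noise draw).
Creatinine is derived by inverting the MDRD equation at the patient's age
and sex, severity groups by KDIGO staging of baseline eGFR, and age runs
8 years higher in the severe-like endotype. The closed-form per-protein R²
of NPX against log2(follow-up eGFR) under this model is

```
R² = (b·v_s)² / (v_x · (b²·v_s + sigma_traj²)),   v_s = e²w(1−w) + sd²/m
```

with `b = trajectory_slope`, `e = effect_size`, `w = mixture_weight`,
`m = n_informative`, `v_x = sd² + e²w(1−w)`. The defaults
(`trajectory_slope = 0.4`, `sigma_traj = 0.1`) were chosen from this formula
to put the expected R² near 0.70 at the strong-effect condition, safely
above the 0.5 the trajectory analysis asserts; the ceiling as
`sigma_traj → 0` is `v_s / v_x` (≈ 0.72 at effect 3), so per-protein R²
cannot approach 1 no matter how strong the coupling — individual proteins
keep their own assay noise.

**Senescence labels.** Exactly `round(13/16 · n_informative)` informative
proteins carry the label, plus 55% of the background — inflammation- and
cardiovascular-panel proteomes are senescence-rich, and this composition
reproduces the qualitative finding that roughly two-thirds of the top-ranked
proteins are senescence-labelled (the shipped fixture gives 0.66 for the
top 50).

**Fixture calibration.** Two shipped properties are calibrated by
construction, not measured into place: heavy-missingness proteins draw their
missing fraction uniformly in [0.25, 0.45] so the >20% completeness cut
always removes them (59 planted on 535 give 476 survivors); and the default
`effect_size = 2.7` puts the silhouette-dilution boundary of forward
selection exactly at the 16 planted proteins (an analytic
mean-squared-distance model locates the boundary; 2.6–2.7 both land on 16,
2.5 stops early, 2.8 runs one long).

**Counts.** The single-cell generator draws negative-binomial counts
(size 10) with log-normal gene baselines, per-cell-type log-normal gene
modulation, and log-normal per-cell library factors (well over 4-fold
spread); an injury signature multiplies `n_de_genes` genes by `2^lfc` in
case samples. Starved samples (library factors × 0.002) exercise
low-expression removal.

**What the generator does not emulate:** realistic proteome covariance
(proteins are conditionally independent given the endotype), batch and plate
effects, assay limits of detection, longitudinal measurements beyond one
follow-up, and cell-type-specific injury responses. Passing recovery tests
therefore show the pipeline recovers the structure it assumes — not that the
assumptions hold in any particular cohort.

## Numerical and design choices

**">80%" is strict.** A protein observed in exactly 80% of patients is
dropped; 63/79 (79.7%) fails, 64/79 (81.0%) passes. The boundary is
unit-tested.

**Proteins are z-scored before PCA and clustering.** NPX baselines differ
per assay; unscaled PCA would rank proteins by variance rather than class
signal. `scale = FALSE` preserves the alternative (and, for clustering,
leaves the matrix completely untransformed so degenerate closed-form checks
hold).

**"Most class variance"** is operationalised as the largest one-way ANOVA F
of PC scores across severity groups over the first 10 PCs, ties toward the
lower index. When severity separates along PC1 — the typical case — this
reduces to PC1.

**Bootstrap sign alignment.** PC signs are arbitrary, so each bootstrap
loading vector is flipped to positively correlate with the full-data vector
before taking absolute values. Absolute values alone already protect the
median; alignment is belt-and-braces and costs nothing.

**Forward selection scans a bounded window.** The spec of the procedure is
"the longest prefix that clusters effectively"; the implementation grows the
panel and stops after 5 consecutive failing steps (or 40 proteins), since
silhouette decays monotonically once uninformative proteins dilute the
panel. Per-(step, k) silhouettes are retained for plotting, and the per-k
criteria (mean silhouette, Calinski–Harabasz, within-cluster SS) are
reported for the final panel.

**The silhouette gate is not a null guard.** K-means on a *single* protein
fragments any 1-D sample into well-separated intervals — mean silhouettes of
0.53–0.60 arise on pure noise — so a tiny panel can pass the 0.5 threshold
with no real structure. What fails on a null cohort is *recovery*: the
resulting clusters are unrelated to any planted labels (ARI ≈ 0). Null
behaviour of the discovery pipeline should therefore be judged against
labels, not against the gate erroring.

**DE under selection.** The type-I control experiments test the DE engine
with cohort assignment given (the generator's labels under a zero effect).
Testing clusters *selected* on the same data would measure post-selection
inflation — a known property of cluster-then-test workflows, not of the
Welch/BH machinery.

**MDRD constant.** The IDMS-traceable re-expressed constant 175 is the
default (186 available via `constant`); µmol/L is converted to mg/dL at
88.4. KDIGO bins are half-open `[lower, upper + 1)`.

**ORA substitutes plain hypergeometric enrichment** for protein–protein
interaction subnetwork methods: the upper-tail `P[X ≥ k]` against the
*assayed* (post-QC) background, BH across terms. Subnetwork-based fold
enrichments from PPI-aware tools are not comparable to these values. The
universe is the measured proteome, not the genome — enrichment against the
genome would mostly rediscover the panel design.

**Pseudobulk DE uses log2(TPM + 1) + Welch** rather than a count model, to
keep one DE engine across the proteomic and transcriptomic stages; this is a
documented divergence from count-based practice (edgeR/DESeq2 dispersion
modelling) and is conservative at the pseudobulk depths the generator
produces. Without gene lengths, TPM falls back to CPM with a warning —
with equal lengths the two are identical anyway. Low-expression removal
drops *whole samples* whose any cell-type row sums below `min_total`
(default 50,000 counts for transcriptome-scale data; set proportionally for
small simulations).

## Problem sizes

The shipped experiments use a 79 × 535 fixture with 500 bootstraps for the
study-scale run; recovery experiments use 80 × 200 cohorts with 10
informative proteins over 20 seeds; type-I and pseudobulk experiments use 10
seeds each (12 samples × 3 cell types × 40 cells × 1000 genes). These sizes
make every property measurable while keeping a full check run to a few
minutes.

## Known limitations

- The silhouette threshold of 0.5 is a convention, not an inferential
  guarantee; small panels can clear it on noise (see above).
- Cluster-then-test DE p-values are not valid for inference on the same
  cohort that defined the clusters; treat them as descriptive rankings.
- The ORA stage assumes symbols match between the proteomic platform and the
  gene-set collection; only exact (optionally case-folded) matching is
  provided.
- MDRD is used for consistency with the clinical tables the method consumes;
  CKD-EPI is not implemented.
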