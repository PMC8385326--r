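# sigtrace

Tracing cell-type signatures from a single-cell atlas into a longitudinal
bulk RNA-seq trial.

## The problem

Anti-integrin therapy in inflammatory bowel disease (e.g. an anti-β7
antibody blocking both α4β7-mediated gut homing and αEβ7-mediated
epithelial retention) is expected to deplete specific T-cell
compartments — above all CD8⁺ intraepithelial lymphocytes (IELs) — from
the gut mucosa. Detecting that depletion in a clinical trial means
connecting two very different data types:

1. a **droplet single-cell RNA-seq atlas** of gut immune cells, from which
   cell-subtype gene signatures are learned, and
2. **paired bulk RNA-seq biopsies** (screening and week 14, colon or
   ileum) from a placebo-controlled trial randomized 1:4
   (placebo:treatment), in which those signatures are scored and tested
   for treatment-specific change.

`sigtrace` implements that full chain as composable, tested R functions,
together with a synthetic-data generator with known ground truth, so every
stage can be exercised and validated without any external download.

## What the package computes

**Single-cell side** (`qc_filter_barcodes`, `normalize_cells`,
`cluster_cells`, `merge_small_clusters`, `rank_sum_markers`,
`build_signature`):

- viable-barcode QC: keep barcodes with ≥ 2000 UMIs and < 8%
  mitochondrial UMIs (both strict in the stated direction);
- per-cell scaling to 10,000 counts + `log1p`; per-donor gene
  standardization; PCA → kNN graph → Louvain clustering;
- the marker-count merge rule: a cluster with fewer than 30 genes at
  ≥ 1.5-fold higher linear-scale expression than the remaining cells is
  merged into its most-correlated neighbour, iteratively;
- one-vs-rest Wilcoxon rank-sum markers (exact enumeration for groups
  ≤ 10, tie-corrected normal approximation otherwise) and signatures of
  at most 50 genes with FDR < 0.01 and positive fold change, ordered by
  fold change.

**Bulk side** (`filter_genes`, `voom_weights`, `fit_and_moderate`,
`call_treatment_modulated`, `de_active_vs_inactive`):

- gene inclusion: > 10 reads in > 31 samples (thresholds configurable);
- log2-CPM with precision weights from the lowess mean-variance trend
  (observation weight = predicted sd⁻⁴), gene-wise weighted least squares
  with covariates *arm + prior anti-TNF + location + visit + arm×visit*,
  empirical-Bayes variance moderation (moment matching on log variances),
  Benjamini–Hochberg adjustment;
- the three-clause treatment call: |fold change| ≥ 1.5 **and** combined
  FDR < 0.05 **and** nominal p < 0.05 in both the colon-only and
  ileum-only analyses;
- a screening-only active-vs-inactive model (activity from the segment
  score rule: colonic score ≥ 7, ileal score ≥ 4).

**Signature scoring and trial readout** (`eigengene_score`,
`paired_change`, `compare_arms`, `score_all_signatures`,
`concordance_analysis`):

- eigengene scores: first right singular vector of the z-scored
  signature submatrix, sign-oriented to the mean signature profile and
  reported on the z scale;
- per-patient week-14 − screening score changes from same-segment pairs
  (by default restricted to endoscopically active screening segments),
  Welch t-test treatment vs placebo per signature with BH across
  signatures;
- per-gene concordance between treatment-induced and
  disease-activity-associated log2 fold changes (the inverse-correlation
  readout of a treatment that resolves inflammation).

The generator (`sim_config`, `simulate_single_cell`, `simulate_trial`)
plants all of this structure — negative-binomial counts, marker genes,
low-quality barcodes, Dirichlet cell-type mixtures, a 1:4 randomized
paired trial with a configurable depletion of one cell type and an
inflammation program tied to activity labels — and returns the ground
truth alongside the data.

## Worked example

```r
library(sigtrace)

cfg <- sim_config(n_genes = 800, cells_per_type = 150, n_patients = 50,
                  mito_gene_count = 20, n_activity_genes = 60)
run <- run_pipeline(pipeline_config(seed = 1), cfg)
run
#> <sigtrace_run>
#>   clusters after merging : 5
#>   signatures             : 5
#>   genes tested (bulk)    : 800
#>   treatment-modulated    : 40
#>   concordance r (treatment): -0.928 (n = 800)
#>   concordance r (placebo): -0.083 (n = 800)

tidy(run$scores)
#> # A tibble: 5 × 9
#>   signature    delta_treatment delta_placebo   diff     t  p_value ...
#> 1 CD4_Treg               1.04         0.153   0.891  4.85 0.00109
#> 2 CD4_effector           0.874        0.0989  0.776  3.23 0.0143
#> 3 CD8_IEL               -0.719        0.375  -1.09  -5.28 0.000543
#> 4 CD8_LP                 0.997        0.176   0.820  4.78 0.000442
#> 5 ILC3                   0.985       -0.191   1.18   4.28 0.00261
```

Reading the output: the five planted cell types were recovered as five
clusters and converted into signatures; 40 genes pass the three-clause
treatment call; the **CD8_IEL** signature — the type whose proportion the
generator halves at week 14 in the treatment arm — is the only signature
with a negative treatment-arm score change (`delta_treatment = -0.72` on
the z scale), and the treatment-vs-placebo difference is significant
(p ≈ 5e-4). The strong negative treatment-arm concordance (r ≈ −0.93)
with near-zero placebo concordance reflects the planted resolution of the
inflammation program under treatment. The other signatures drift slightly
upward because proportions are compositional: depleting one type inflates
the rest.

Each result object has `tidy()` / `glance()` methods and an `autoplot()`
(volcano plot for differential-expression fits, per-arm delta boxplots for
signature comparisons, fold-change scatter for concordance results).

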