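---
title: "Methods: from single-cell signatures to trial-level treatment effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from single-cell signatures to trial-level treatment effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`sigtrace` chains two analyses that are usually run separately: learning
cell-subtype gene signatures from droplet single-cell RNA-seq, and
quantifying a treatment's effect on those subtypes in paired bulk RNA-seq
biopsies from a randomized trial. This vignette documents the statistical
model at each stage, the parameters that matter and why their defaults
are what they are, what the synthetic-data generator does and does not
emulate, and the design decisions taken where the problem was genuinely
open.

## 1. Single-cell stage

### Quality control

A barcode is considered to contain a viable cell when it has at least
2000 UMIs **and** strictly less than 8% of UMIs from mitochondrial genes.
Both comparisons are deliberately strict on the stated side: a barcode
with 1999 UMIs or with exactly 8% mitochondrial content is removed. These
are the standard cutoffs for fresh gut biopsy material, where dying
epithelial-contaminated droplets show high mitochondrial load and
ambient-only droplets show low totals; the two clauses catch those two
failure modes independently.

### Normalization and clustering

Counts are scaled per cell to a fixed total of 10,000 and transformed
with `log1p` — the documented default behaviour of the major single-cell
toolkits. This is scale-free within a cell (proportional count vectors
normalize identically) and monotone in counts.

Cross-donor alignment is performed by standardizing each gene within each
donor (zero mean, unit variance per donor) before PCA. This removes
multiplicative donor offsets exactly and is a deliberate simplification
of canonical-correlation-based alignment: the synthetic data contain only
mild donor offsets by design, and a full CCA reimplementation would add
substantial machinery without changing what the downstream tests can
show. On real multi-donor data with strong batch structure, users should
expect this step to be the weakest link and may substitute externally
aligned embeddings.

Clustering is Louvain community detection on an unweighted k-nearest-
neighbour graph (Euclidean distance in the top 20 PCs; k = 15), run at
resolution 0.3. "Low" resolution is intentional: the goal is broad cell
types, and the merge rule below removes residual oversplitting. The
community search is seeded, and a fixed seed reproduces labels exactly.

### The marker-count merge rule

A cluster is only biologically interpretable as a cell type if enough
genes distinguish it. After clustering, each cluster is tested for the
number of genes whose linear-scale mean expression in-cluster is at least
1.5 times the mean over all other cells (pseudocount 1e-9 in the
denominator). A cluster with fewer than 30 such genes is merged into the
cluster whose log-space centroid is most Pearson-correlated with its own,
and the procedure repeats until all clusters pass or one remains. A
cluster with exactly 30 qualifying genes is retained.

Two details are genuinely underdetermined and were fixed as follows:

- *Scale of the fold change.* Whether the 1.5-fold test is applied to
  linear or log expression is not standard; this implementation uses
  linear-scale means of the normalized expression, since fold-change
  thresholds in marker selection conventionally refer to linear ratios.
- *"Most similar" cluster.* Pearson correlation of centroids in
  normalized log space, chosen because it is invariant to the overall
  expression magnitude of the clusters being compared.

The procedure terminates in at most (initial clusters − 1) merges because
each iteration strictly decreases the cluster count.

### Markers and signatures

Marker statistics are one-vs-rest two-sided Wilcoxon rank-sum tests per
gene. When both groups have at most 10 cells the p-value is computed by
full enumeration of all C(n₁+n₂, n₁) assignments of the pooled mid-ranks
(exact under ties); otherwise the normal approximation with mid-ranks and
tie-corrected variance is used, without continuity correction. Fold
changes are linear-scale ratios of within/without means. P-values are
BH-adjusted within each cluster's gene family.

A subtype signature keeps genes with FDR < 0.01 **and positive** fold
change, ordered by descending fold change, truncated at 50 genes. "Most
differential" is interpreted as largest positive fold change (rather than
smallest p) because signatures must mark *presence* of a cell type in
bulk tissue: a gene that is significantly depleted in a type would
corrupt an abundance score. Ties at the truncation boundary are broken by
gene identifier so signature construction is deterministic.

## 2. Bulk stage

### Gene filter, transformation, weights

Genes enter the analysis when they have more than 10 reads in more than
31 samples — both strict. The 31 is cohort-specific (roughly a quarter of
the motivating cohort's samples); `min_samples` should be rescaled for
other cohorts, and the in-package analyses default to half of the
samples in the stratum being analysed.

Expression is modelled on the log2-CPM scale with pseudocounts
(count + 0.5, library + 1). Because the variance of log2-CPM depends
systematically on abundance, each observation receives a precision
weight: a gene-wise linear model is fitted, the square root of the
residual standard deviation is smoothed against average log2 count by
lowess (span 0.5), and the weight of each observation is the predicted
standard deviation at its fitted log-count, raised to the power −4. A
flat trend therefore yields near-constant weights, and weights increase
along a decreasing mean-variance trend. The test suite verifies this
implementation against the reference implementation in `limma::voom` to
numerical tolerance.

### Linear model and moderation

The treatment analysis uses fixed effects only: arm, prior anti-TNF
incomplete response, biopsy location (dropped in single-location strata),
visit, and the arm×visit interaction, all coded 0/1 with the interaction
as their product. The interaction coefficient *is* the treatment-specific
expression change and is the tested contrast; this is also the "fold
change" to which the 1.5 threshold of the treatment call is applied (the
modelled treatment-specific effect, not the raw within-arm change). No
patient-level random effect is included — a deliberate simplification
documented here: with exactly two exchangeable visits per patient the
fixed-effects interaction estimate is unbiased, at some cost in power
relative to a paired model.

Gene-wise residual variances are moderated by empirical Bayes: the prior
degrees of freedom and prior variance are estimated by matching the first
two moments of the log residual variances to a scaled-F model (digamma /
trigamma moment equations, Newton inversion of the trigamma function),
and posterior variances are the df-weighted average of gene and prior
variances. Moderated t statistics use residual + prior degrees of
freedom. Two boundary behaviours are built in deliberately: forcing the
prior df to zero recovers the ordinary t-test exactly, and when the
observed log-variance spread is at or below its pure-sampling expectation
the prior collapses onto the geometric mean of the observed variances, so
"all gene variances equal" is an exact fixed point of moderation.

Samples enter the treatment analysis only when both visits are available
from the same bowel segment and (by default) the screening biopsy came
from an endoscopically active segment; activity is defined by the segment
score rule — colonic score ≥ 7, ileal score ≥ 4, both inclusive. The
active-vs-inactive model uses screening biopsies only, with location and
anti-TNF as covariates; week-14 samples can never influence it.

### The three-clause treatment call

A gene is called treatment-modulated when |log2FC| ≥ log2(1.5) in the
combined two-location analysis, combined FDR < 0.05, and unadjusted
p < 0.05 in both the colon-only and ileum-only analyses. The per-location
nominal clauses act as replication filters: a hit driven by one segment
type alone does not survive. Under the null generator this call returns
essentially zero genes (mean 0.05 per 2000-gene replicate across 20
seeds in the acceptance suite).

## 3. Signature scoring and the trial readout

A signature score is the first right singular vector of the gene-wise
z-scored signature submatrix, scaled by √(n−1) so it lives on the z scale
and sign-oriented so it correlates nonnegatively with the mean z-scored
signature profile. Consequences used as tests: when all signature genes
share one profile the score *is* that profile z-scored; scores are
invariant to per-gene affine transforms and to gene order (including the
sign). Signature genes absent from the matrix are dropped with a warning
when at least half remain, otherwise scoring errors out listing the
missing genes; zero-variance genes are dropped with a warning. This
eigengene summarization is a reconstruction of the scoring method the
motivating analysis used by reference; it is validated behaviourally
(score vs true mixing proportion, r ≥ 0.9 on synthetic mixtures) rather
than by numeric identity to any specific package.

Per-patient changes are week-14 minus screening scores from same-segment
pairs, with the same active-screening inclusion rule as the gene-level
analysis; the arm contrast is a Welch t-test (treatment minus placebo) by
default — chosen over the pooled-variance test because arm sizes are
unbalanced by design (1:4) — with Student's version available. Per-gene
paired changes (`treatment_change_per_gene`) use mean week-14 − screening
log2-CPM; the paired change is computed *on scores* for signatures, with
the per-gene route available for gene-level displays.

### Concordance and the choice of gene universe

The concordance analysis correlates per-gene treatment changes with the
activity coefficient from the screening-only model. Two gene universes
are supported: all filtered genes, and the treatment-modulated subset.
The pipeline default is **all genes**. The reason is a selection effect
that the synthetic ground truth makes visible: the modulated-gene call
conditions on the arm×visit interaction, into which placebo paired
deltas enter with negative sign, so restricting the *placebo*-arm
correlation to called genes induces a spurious positive correlation
(0.2–0.8 across seeds) even when the placebo arm is exactly null. The
all-genes variant is unbiased in the placebo arm (|r| < 0.1 across
seeds) and matches the per-gene scatter display this readout mirrors.
The restricted variant remains available for the treatment arm, where it
sharpens the signal (r ≈ −0.92 at defaults).

## 4. The synthetic-data generator

The generator is first-class, tested code: it defines the study
conditions under which every downstream claim is verified.

*Single-cell:* 5 cell types (a CD8-IEL-like target plus CD8-LP,
CD4-effector, CD4-Treg and ILC3-like types), 2000 genes, 40 disjoint
marker genes per type at 8-fold elevation, 300 cells per type, NB counts
with dispersion 0.1, library sizes log-normal around 8000 UMIs, 4 donors
with mild (5% log-sd) multiplicative offsets, and 10% low-quality
barcodes split between a low-UMI flavour (~700 UMIs) and a
high-mitochondrial flavour (~20% mitochondrial share against ~2% for
viable cells) so each QC clause is exercised separately. Forty markers
per type is the smallest round number comfortably above the 30-gene
merge-rule requirement — a type with fewer distinguishing genes than the
merge rule demands would be unretainable by construction.

*Trial:* 100 patients (the scale of the motivating cohort's paired
subset; the full cohort enrolled 350) randomized exactly 1:4, one
screening and one week-14 biopsy per patient from the same segment
(colon or ileum), patient-level Dirichlet(10) mixtures over the same
five expression programs (between-patient proportion CV ≈ 0.3, a
realistic degree of compositional variability), bulk libraries
log-normal around 2×10⁶. Treatment multiplies the target type's
proportion by `effect_size` (default 0.5) at week 14 only, with
renormalization; a latent per-patient severity is thresholded through
the segment-score rule to produce activity labels, and 100 activity
genes are elevated 4-fold in active biopsies — mucosal inflammation
programs in IBD span roughly 2–10-fold, and 4 leaves the
interaction detectable at this cohort size under the fixed-effects
model. Treatment also multiplies the latent severity by `effect_size`,
so the inflammation program resolves specifically under treatment; with
`effect_size = 1` the generator is exactly null (identical proportions
and severity at both visits), which is what the type-I-error suite runs
on.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: doublets and ambient RNA; batch effects beyond
donor offsets; overlapping or correlated marker programs between types;
gene–gene correlation beyond the mixture structure; patient dropout and
missing visits; sequencing-run batch structure; and any real biological
annotation of the planted gene sets. Claims about robustness to those
features require real data.

## 5. Numerical choices and degenerate inputs

- Pseudocounts: 0.5 on counts and 1 on library sizes inside log2-CPM;
  1e-9 in every linear-scale fold-change denominator.
- Lowess span 0.5 for the mean-variance trend; trend predictions floored
  at 1e-6 before the −4 power so weights stay finite and positive.
- Exact Wilcoxon enumeration switches on when both groups have ≤ 10
  observations; two-sided p is 2·min(lower tail, upper tail) capped
  at 1, with a 1e-9 tolerance around the observed statistic.
- A single-gene matrix cannot support a trend: unit weights are returned
  with a warning. Rank-deficient designs error, naming the aliased
  columns. Zero-variance arms in the t-test return difference 0 and
  p = 1 with a warning rather than failing.
- All label re-indexing (clusters) is contiguous from 0 and ordered by
  original label, so repeated runs are stable.
- Seeds: every stochastic step takes an explicit seed; the pipeline fans
  per-stage seeds out deterministically from one global seed, and reruns
  are byte-identical.

## 6. Problem sizes used in validation

The shipped validation suite runs the full single-cell chain at the
default 2000 × ~1670 scale once, the trial chain at 100 patients, a
20-replicate null ensemble for type-I error, and reduced configurations
(600 genes, 100 cells/type, 30 patients) for the many structural and
round-trip checks — sizes chosen so the complete suite documents the
method's behaviour in about a minute of compute while the headline
recovery checks still run at the generator's default study scale.

## 7. Known limitations

- Fixed-effects modelling of paired biopsies forgoes the power of an
  explicit within-patient correlation structure.
- The donor-standardization stand-in for cross-donor alignment is
  adequate for multiplicative offsets only.
- Eigengene scores are unit-scale summaries: they rank samples by
  signature activity but are not calibrated cell-type proportions, and
  compositional coupling means depleting one type raises the scores of
  the others.
- The merge rule tests marker counts against the pooled complement, so a
  rare type nested inside a large similar type can be absorbed.
- Exact Wilcoxon enumeration is combinatorial; it is restricted to tiny
  groups by design.
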