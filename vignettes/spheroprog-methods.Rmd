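---
title: "Methods: expression-program discovery in tumor spheroid scRNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: expression-program discovery in tumor spheroid scRNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(spheroprog)
```

This vignette documents the models and procedures the package implements,
the assumptions behind them, the tunable parameters and their defaults, and
the design decisions taken where a convention had to be fixed. Nothing here
states an empirical result beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## 1. The analysis problem

Patient-derived colorectal cancer spheroids are pure tumor-cell cultures
whose cells occupy distinct differentiation compartments (stem-like,
TA-like, Paneth-like, Tdiff-like) overlaid by cell states (cell cycle,
OXPHOS, hypoxia/glycolysis). Two statistical obstacles dominate:

* **Inter-patient variation dwarfs within-patient heterogeneity.** Cells
  cluster by patient long before they cluster by cell type. Programs shared
  across patients are therefore inferred from *per-patient mean-centered*
  expression.
* **Program activity is graded and confounded by library complexity.** A
  cell's mean expression over a gene set rises with detected-gene count
  regardless of biology, so scores are corrected against expression-matched
  random control genes, and activity is declared only above an explicit
  threshold.

## 2. Preprocessing

Normalization is `E = log2(CPM/10 + 1)`; the divisor 10 stops low-depth
noise from inflating log-scale variance. CPM denominators are computed
before any gene filtering, so dropping genes later does not change retained
values.

**QC** keeps cells with strictly more than 100,000 reads and 1,000 detected
genes and strictly less than 15% mitochondrial reads (mitochondrial genes
recognized by the `MT-` symbol prefix — the standard human annotation; no
list is configurable because none is needed for synthetic data). The
deepest 5% of libraries are removed within each patient independently
(multiplet enrichment); with `n` surviving cells the rule removes
`floor(0.05 n)`, ties broken by stable cell order. All criteria are
evaluated on the full input and intersected before the per-patient rule
runs on the survivors, making the filter order-independent. An optional
PCA-outlier rule (cells whose distance from the centroid in top-10 PC space
exceeds the mean by `k` SDs) ships disabled: dropping cells on an
unspecified criterion by default would be silent data loss.

**Gene filtering** removes weakly expressed genes by aggregate expression
`Ea` with cutoff 3.5 (strict: a gene exactly at the cutoff stays). Two
aggregation conventions exist because the formula can be read two ways:

* `aggregate = "linear"` (default): `Ea = log2(mean(CPM/10) + 1)`, the mean
  taken on the linear scale. The cutoff then corresponds to mean CPM ≈
  103 — an "intermediately-to-highly expressed" gene set large enough to
  carry 200-gene signatures.
* `aggregate = "log"`: `Ea = log2(mean(E) + 1)`, the mean of the log values
  themselves. Because per-cell E values are bounded by the library (the sum
  of linear CPM is fixed at 10⁶), requiring `mean(E) ≥ 2^3.5 − 1 ≈ 10.31`
  caps the retained set at roughly 78 genes regardless of cohort — too few
  to support top-200-gene signatures. The mode is kept for boundary
  analysis and unit-tested exactly, but it is not the default because it is
  internally inconsistent with signature extraction.

**Culture gating**: a culture is analyzed only if its LGR5 score (total
LGR5 transcript counts / cell number) is strictly greater than 1. A score
of exactly 1 is negative; the shipped per-culture table reproduces the
8-positive / 4-excluded split of the twelve-culture cohort under this rule.

**Differential expression** is per-patient one-vs-rest Wilcoxon with BH
adjustment *within each patient contrast* (the reported lists are
per-patient top-10 tables, so the FDR unit is the contrast), filtered at
adjusted p < 0.05 and log-FC > 0.25 (both strict).

## 3. NNMF and factor curation

The centered matrix (negatives clipped to 0) is factorized as `V ≈ W H`
with `k = 25` factors by default. The fitter is alternating least squares
with projection to the non-negative orthant, random uniform initialization,
10 restarts, tolerance 1e-4 on relative error change, and at most 500
iterations. Projected ALS does not guarantee monotone error, so each
iteration that would increase the Frobenius error is reverted and the
restart stops; the recorded trace is therefore non-increasing and the best
restart is returned. All randomness is local to the call (seeded, global
RNG state restored).

**Patient-specific factors** are removed by distribution overlap: for each
factor, per-patient histograms of its cell scores on 50 shared equal-width
bins spanning the pooled range; the overlap of two patients is the sum of
bin-wise minima of the normalized histograms (histogram intersection, in
[0,1]). A patient *fails* a factor when its median overlap with the other
patients is below 0.5; a factor is excluded when at least `min_patients =
5` patients fail. The printed rule reads this way, but note the logical
tension: a factor private to a *single* patient produces exactly one
failing patient and survives the literal rule. Both behaviors are exposed —
`min_patients = 1` gives the stricter "any patient separates" variant — and
the default follows the literal rule.

**Signatures** are the top 200 genes per factor by loading, ties broken by
gene identifier; a factor with fewer strictly positive loadings than
requested is flagged degenerate. Signatures whose per-cell score vectors
correlate are merged into meta-signatures by complete-linkage clustering of
`1 − Pearson r`, cut at `1 − 0.6`; the merged gene list orders genes by
their best rank across members.

## 4. Cell scoring and type assignment

Scores are computed on *uncentered* E values: both the "averaged
expression" definition and the background model refer to absolute
expression strata. Genes are ranked by aggregate (linear-scale) expression
into 25 equal-occupancy bins; for each signature gene, 100 control genes
are sampled from its bin (without replacement where the bin allows). The
corrected score is the mean signature expression minus the mean control
expression; a constant matrix scores exactly zero, and a bin-wide additive
shift cancels.

A program is **active** in a cell when its corrected score strictly exceeds
the mean plus one *population* SD of that program's scores across cells
(population rather than sample SD is fixed for reproducibility; at cohort
scale the difference is negligible; zero SD means no active cells). Whether
the threshold should apply to raw or corrected scores is not specified
anywhere; corrected scores are used because the threshold would otherwise
re-import the library-complexity confounder the background model removes.
Cells are assigned to the active type program with the highest corrected
score — an argmax tie-break, because the analysis requires a unique label
per cell — and cells with no active type program stay `unassigned`. State
differences between compartments are tested by two-tailed Mann–Whitney
with per-group medians and quartiles.

## 5. Bulk stratification and survival

Bulk samples are scored as the mean log expression of each signature's
present genes (at least 50% must be present; the missing fraction is
recorded). The six-cluster stratification applies five sequential binary
splits, each a complete-linkage hierarchical clustering cut at two
branches:

1. OXPHOS_1, G1/S, G2/M, stem (Euclidean) — high branch = {cl2, cl3};
2. hypoxia/glycolysis_1, TNFα_2 (Euclidean) within the high branch —
   cl2 low, cl3 high;
3. fatty acid, TNFα_1 (Euclidean) within the rest — cl1 high;
4. stem, TA (correlation distance) — cl6 is the stem-low branch;
5. G1/S, G2/M, OXPHOS_1 (Euclidean) within {cl4, cl5} — cl4 medium,
   cl5 low (branch ranking decides medium vs low; only relative levels are
   defined).

The exact cut convention is not fixed anywhere, and a bare `cutree(k = 2)`
of complete linkage occasionally isolates a handful of extreme samples as
one branch, wholesale-mislabeling a split. Each Euclidean split therefore
consolidates the two-branch cut by nearest-centroid reassignment seeded
from the branch centroids: clean cuts are untouched (the centroid partition
and the tree partition coincide), degenerate cuts are repaired. Step 4 uses
the correlation between the two-signature profiles of samples, which for
two dimensions reduces to the sign of the stem-vs-TA contrast — a
deliberate scale-free split; no consolidation is needed there.

Survival groups are compared by Kaplan–Meier estimates with log-rank tests
(merged contrasts are formed by relabeling before the call), and the
prognostic value of the clusters on top of clinical covariates is the
likelihood-ratio chi-square between nested Cox models (df = parameters
added by the cluster term). The conventional significance level for these
survival analyses is 0.1, kept configurable.

## 6. Limiting-dilution frequency estimation

Under the single-hit Poisson model a well seeded with `d` cells remains
negative with probability `exp(−f d)`; this is preferred over the binomial
`(1−f)^d` variant (available conceptually, numerically indistinguishable at
f ≪ 1) because it is the classical Poisson-statistics formulation. The MLE
is found by Brent search on `log f` followed by Newton refinement of the
score equation (tolerance ~1e-14 relative), so single-dose fits agree with
the closed form `f = −log(1 − r/n)/d` to numerical precision. Confidence
intervals invert the likelihood-ratio statistic at the χ²(1) 0.95 quantile
(3.841) — more robust at small counts than Wald intervals on log f.
Boundary cases are flagged: all-negative assays give `f = 0` with a
one-sided upper bound; all-positive assays give `f = 1` (the domain edge)
with a one-sided lower bound. Two assays are compared by
`2(ℓ_a + ℓ_b − ℓ_pooled)` against χ²(1), and estimates are normalized to a
bulk reference as the ratio of frequencies with the interval propagated as
the ratio of opposite bounds.

## 7. The synthetic-data generator

`generate_spheroid_cohort()` draws counts for gene *i* in cell *j* from a
negative binomial with mean

    lib_j · 2^( b_i + o_{p(j),i} + Σ_k effect_k · active_k(j) · member_k(i) )

* `b_i`: per-gene log2 baseline. Program members are drawn from N(3.5, 1)
  and background genes from N(3, 1.5), so planted biology sits in the
  intermediate-to-high expression range that survives the Ea filter.
* `o`: per-patient per-gene offsets, N(0, 0.5) log2 units — the dominant
  patient-level clustering that centering must remove.
* `lib_j`: log-normal library-size factor (sdlog 0.3).
* Negative-binomial shape 2 captures scRNA-seq overdispersion without a
  separate dropout parameter; shape ∞ gives the Poisson limit.

The default cohort is 8 patients × 200 cells × 1,000 genes with four
50-gene type programs (proportions stem 0.30, TA 0.40, Paneth 0.10, Tdiff
0.20) and three 50-gene state programs, all at effect 2.0 log2 units
(≈4-fold). States are activated per cell by a Bernoulli draw conditioned on
the cell's type. The coupling matrix is graded — states are *enriched in*,
not exclusive to, compartments (TA cells are proliferative and OXPHOS-high,
Tdiff cells hypoxia/glycolysis-high, etc.) — which keeps every planted
program-pair activation correlation at or below ~0.5, i.e., below the 0.6
meta-signature merge threshold: the seven programs are planted as
*distinct* programs, matching how the analysis treats type and state
signatures as separate meta-signatures. The first stem-program gene is
named `LGR5` so culture gating is exercisable. Per-cell `total_reads` is
25× the molecule count and `mito_fraction` is Beta(2, 31) (mean ≈6%), so
realistic cells pass the QC thresholds while edge cases remain testable by
construction. All generative parameters are returned in the ground truth so
marginal moments can be checked against the formula.

What the generator does **not** emulate: ambient RNA, doublets, batch
chemistry, zero-inflation beyond NB, gene-gene correlation within programs
beyond co-activation, or spatial structure. Passing tests therefore show
the pipeline recovers planted structure under idealized noise — not that it
is robust to every artifact of real libraries.

`generate_bulk_cohort()` plants six cluster archetypes on nine signatures
with Gaussian noise and exponential survival (cluster-specific hazards,
independent exponential censoring). The archetype magnitudes encode the
qualitative high/medium/low profiles that define cl1–cl6 and were fixed
once by a separability study: magnitudes were chosen so the six archetypes
are well separated under the progressive splitting scheme at noise SD 0.5
(e.g., the cl4/cl5 "medium vs low" gap spans the cohort average, and the
stem-vs-TA contrast in stem-high clusters is wide enough that noise rarely
flips its sign). The default hazard ratios (cl1–cl3 = 1, cl4 = 2,
cl5 = 2.5, cl6 = 3) give the stem-low/low-proliferation clusters the poorer
outcome, matching the direction of the prognostic association the
stratification is meant to detect.

## 8. Problem sizes and numerical choices

The end-to-end recovery analyses (tests and `scripts/acceptance.R`) run the
default 8 × 200-cell cohort with `k = 12`, 3 restarts, 300 iterations and
50-gene signatures: on a 1,000-gene panel, 50-gene signatures match the
planted program size (200-gene signatures would dilute the Jaccard metric
with filler), `k = 12` comfortably exceeds the 7 planted programs plus
patient residue, and the detected-gene QC floor is 300 (the published
1,000-gene floor assumes a genome-wide panel). Dilution coverage uses 1,000
simulated assays at f = 1/50 under the standard 48/24/16-well layout;
clustering uses 60 samples per archetype. These sizes were chosen as the
smallest at which the Monte-Carlo error of each check is clearly below its
acceptance margin.

Other fixed conventions: strict inequalities exactly as printed everywhere
(boundary behavior is unit-tested); gene identifiers are case-sensitive and
matched by exact string; all file writes are atomic (temp file + rename);
ALS ridge 1e-10 for numerical stability of the normal equations; histogram
overlap returns 1 for a factor with zero score range (no evidence of
patient specificity).

## 9. Known limitations

* NNMF is a local optimizer; restarts mitigate but do not guarantee the
  global optimum, and factor splitting of one biological program across
  factors is expected (handled by meta-signature merging).
* The literal ≥5-failing-patients exclusion rule cannot remove a factor
  private to fewer than five patients; use `min_patients = 1` when that
  matters.
* The progressive stratification hard-codes the published split order and
  signature roles; it is not a general-purpose clusterer.
* Likelihood-ratio CIs for dilution assays are asymptotic; at very small
  well counts coverage can deviate from the nominal level.
* The generator's idealizations (Section 7) bound what green tests imply
  about real data.
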