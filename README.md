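# spheroprog

Dissecting intra-tumor heterogeneity in patient-derived colorectal cancer
(CRC) spheroid cultures from multi-patient single-cell RNA-seq, and linking
the discovered expression programs to bulk-cohort survival and to functional
stem-cell frequencies.

CRC spheroid cultures are pure tumor-cell models that retain a
differentiation hierarchy reminiscent of the normal intestinal epithelium:
LGR5⁺ stem-like cells, proliferative transit-amplifying (TA-like) cells,
niche-supporting Paneth-like (deep crypt secretory-like) cells, and
terminally differentiated (Tdiff-like) cells, overlaid by metabolic and
proliferative cell states (cell cycle, OXPHOS, hypoxia/glycolysis). Because
single-cell expression is dominated by inter-patient differences, programs
shared across patients only emerge after per-patient centering; because
program activity is graded, assigning cells to types needs a
background-controlled score and an explicit activity threshold.

## What the package computes

**Preprocessing.** Per-library QC (strictly >100,000 reads, >1,000 detected
genes, <15% mitochondrial reads; per-patient removal of the top 5% deepest
libraries), normalization

    E[i,j] = log2(CPM[i,j] / 10 + 1),

aggregate-expression gene filtering (genes with Ea < 3.5 excluded, where
Ea = log2(mean(CPM/10) + 1) across all cells), culture gating by the LGR5
score (total LGR5 transcripts / cell number, strictly > 1), per-patient
mean-centering Er[i,j] = E[i,j] − mean(E[i,·]), and per-patient one-vs-rest
Wilcoxon differential expression (BH-adjusted p < 0.05, log-FC > 0.25).

**Program discovery.** Non-negative matrix factorization of the centered
matrix (negatives clipped to 0), `V ≈ W H` with k factors, alternating least
squares, multiple seeded restarts. Factors whose per-patient cell-score
distributions fail a histogram-intersection overlap rule (< 50% overlap in
at least five patients) are excluded as patient-specific. Each retained
factor yields a signature (top 200 genes by loading); signatures whose
per-cell scores correlate (complete linkage, cut at 1 − r) merge into
meta-signatures. Cells are scored as the mean signature expression minus the
mean of expression-bin-matched random control genes; a program is *active*
in a cell when its corrected score exceeds the mean + 1 SD across cells, and
each cell is assigned to its highest-scoring active type program. State
differences between compartments are tested by two-tailed Mann–Whitney.

**Bulk cohorts.** Signature scoring of bulk transcriptomes (mean expression
of signature genes), a progressive six-cluster stratification (five
sequential binary splits on named signature sets), Kaplan–Meier / log-rank
survival comparison, and likelihood-ratio comparison of nested Cox models
with and without the cluster labels.

**Limiting dilution.** Single-hit Poisson estimation of sphere-forming /
tumor-initiating cell frequency: a well seeded with d cells stays negative
with probability exp(−f·d); f̂ maximizes

    Σ_d [ r_d·log(1 − e^(−f·d)) − (n_d − r_d)·f·d ],

with likelihood-ratio 95% confidence intervals, boundary handling,
likelihood-ratio comparison of two assays, and normalization to a bulk
reference.

**Synthetic data.** Seeded generators for multi-patient count matrices with
planted type/state programs (negative-binomial counts, per-patient offsets,
library-size variation), bulk cohorts with archetype-shifted signatures and
cluster-dependent exponential survival, and dilution assays — so every stage
is testable without external downloads.

## Worked example

```r
library(spheroprog)

cfg <- spheroid_sim_config(n_patients = 4, cells_per_patient = 150, seed = 11)
sim <- generate_spheroid_cohort(cfg)
lgr5_score(sim$counts)
#>   patient    score n_cells positive
#> 1     P01 14.64667     150     TRUE
#> 2     P02 15.04000     150     TRUE
#> 3     P03 24.44667     150     TRUE
#> 4     P04 20.84667     150     TRUE

pc  <- pipeline_config(min_genes = 300, k = 10, n_restarts = 2,
                       max_iter = 300, signature_top_n = 50,
                       min_patients = 3)
res <- run_pipeline(sim$counts, pc)
res
#> pipeline_result: 548/600 cells passed QC, 548 analyzed;
#>   940/1000 genes kept; 10/10 factors retained; 9 meta-signature(s)

ev <- evaluate_program_recovery(res, sim$truth)
round(ev$jaccard, 2)
#>               stem                 TA             Paneth              Tdiff
#>               1.00               0.61               1.00               1.00
#>         cell_cycle             OXPHOS hypoxia_glycolysis
#>               1.00               1.00               1.00
ev$accuracy
#> [1] 0.89
```

Every culture passes the LGR5 gate (scores 14.6–24.4 transcripts/cell, all
strictly above 1), 548 of 600 cells survive QC, and each of the seven
planted programs is recovered as a meta-signature whose top genes overlap
the planted gene set (Jaccard 0.61–1.00); 89% of cells are re-assigned to
their true compartment.

Limiting dilution, with the standard in vitro layout (48 wells × 10 cells,
24 × 100, 16 × 1000):

```r
est <- estimate_frequency(dilution_assay(dose     = c(10, 100, 1000),
                                         tested   = c(48, 24, 16),
                                         positive = c(7, 20, 16)))
est
#> frequency_estimate: f = 1/58.2 (95% CI 1/89.6 - 1/39.2)
```

i.e., about one sphere-forming cell per 58 seeded cells.

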