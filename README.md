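# discproteome

Spatial proteomic analysis of the human intervertebral disc (IVD): an R
package implementing the full analysis chain for label-free quantification
(LFQ) proteomes sampled across the disc's anatomy — from missing-value
handling through dropout-aware differential expression and spatial module
trends to a LASSO model linking the extracellular-matrix (ECM) proteome to
MRI intensity — together with a synthetic-disc generator with known ground
truth that makes every stage testable.

It is written for computational proteomics researchers working with
spatially resolved LFQ matrices (MaxQuant proteinGroups or plain TSV) with
anatomical metadata, and for methodologists who want a reference
implementation of the dropout-aware analysis design.

## The methods at the core

Given a protein × profile matrix of log2 LFQ values with missingness mask,
anatomical labels (age, lumbar level, compartment NP / NP/IAF / IAF / OAF,
direction, axis position), and matrisome annotation:

* **Protein selection** — proteins sorted by valid-value count; the cutoff
  keeps every protein with valid count v > n/2, the point past which each
  additional protein adds more missing than observed cells.
* **Imputation** — chained equations with predictive mean matching
  (k = 5 donors, ≤ 50 sweeps, multiple imputations pooled by cell-wise mean).
* **Ordination** — profile-standardised PCA (population SD), with degree-2
  polynomial-kernel SVM decision boundaries and probability contours at
  0.25/0.5/0.75 between age groups, compartments, or levels.
* **Variance partitioning** — per-protein one-way ANOVA per factor on
  observed values; eta² aggregated by matrisome category.
* **Differential expression** — the three-tier dropout-aware caller: t-test
  with BH FDR < 0.05 where both groups are detected in > half of profiles;
  exclusive detection (> half vs zero); fold change ≥ 2 where both groups
  are sparse. A built-in 23-comparison scheme yields the DEP union
  ("variable set") and the well-detected non-DEPs ("constant set").
* **Spatial modules** — hierarchical clustering with (1 − correlation)
  distance; per-module z-scores pooled along the lateral or anteroposterior
  axis; Gaussian-process trend fits (squared-exponential kernel + nugget,
  marginal-likelihood hyperparameters) with ±1 SD bands and
  concave/convex/flat shape classification; young-vs-aged amplitude ratios.
* **Cellularity** — histone/GAPDH/ACTA2 marker indices with exact Wilcoxon
  rank-sum contrasts.
* **MRI link** — region-wise mean pixel intensity over image stacks,
  level × location biclustering, the "hydration matrisome" (ECM proteins
  correlated with region intensity, p < 0.05), and a cross-validated LASSO
  trained on the aged cohort and evaluated on the young one (Pearson /
  Spearman / IAF-vs-OAF ROC AUC).

## Worked example

The `analysis/` scripts run the whole workflow on a synthetic disc cohort
(`Rscript analysis/01_simulate.R` … `06_mri_hydration.R`, writing under
`results/`). Highlights of an actual run (seed 1):

```
Simulated 612 proteins x 66 profiles; 18.0% of cells missing.
Cutoff keeps 526 of 612 proteins (96.1% of valid cells, 39.7% of missing cells).
PC1/PC2/PC3 explain 17.7% / 13.0% / 7.7% of variance.
DEP calls by strategy: exclusive=47, fold_change=331, statistical=340.
Young proteome partition: 161 variable, 419 constant, 32 marginal.
Module 4: concave (young) -> concave (aged), amplitude ratio 0.69.
Histone index, young vs aged: Wilcoxon p = 9.67e-05 (n = 33/33).
GAPDH ~ ACTA2 co-expression: r = 0.748 (p = 5.29e-13, n = 66).
Hydration matrisome: 28 candidate ECM proteins (11 positive, 17 negative).
Cross-age prediction on young discs: PCC 0.625 (p = 1.0e-04), Spearman 0.632.
```

Read: of the planted spatial structure, the concave NP-high module keeps its
shape but loses amplitude in the aged discs (ratio 0.69 < 1, the planted
flattening); histone-inferred cellularity drops significantly with age; and
an ECM model trained on aged MRI intensities transfers to the young cohort
with PCC 0.63. In code, a single stage looks like:

```r
library(discproteome)
sim  <- generate_disc_dataset(synthetic_config(seed = 1))
meta <- sim$matrix$profiles
cmp  <- make_comparison("OAF_vs_inner",
                        meta$profile_id[meta$compartment == "OAF"],
                        meta$profile_id[meta$compartment != "OAF"])
deps <- call_deps(sim$matrix, cmp)
table(deps$strategy)
```

`run_pipeline(out_dir, synthetic_config(seed = 1))` executes all stages in
dependency order and writes a manifest with file checksums; reruns with the
same seed are bit-identical.

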