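# MarrowDivergence

Statistics for asking whether one bone-marrow compartment — in particular
the skull (calvaria) — transcriptionally diverges from other bones in
multi-region, multi-condition single-cell RNA-seq designs (e.g. naive /
sham / MCAo stroke cohorts spanning calvaria, scapula, humerus, vertebra,
pelvis, femur, dura mater and brain).

The package implements, as reusable tested R code:

- **Divergence score with permutation null.** For the cells of one cell
  type, PCA is computed once (up to 50 components) and for each region the
  one-region-vs-rest indicator is regressed on every component:

  V = Σ_j R²_j λ_j / Σ_j λ_j,

  where R²_j is the squared Pearson correlation between component *j*'s
  scores and the binary indicator and λ_j the component's explained
  variance. Region labels are permuted (default 1000×); p = k/n_perm with k
  the number of permuted scores ≥ the observed one, and only k = 0 (p <
  0.0001) counts as significant. Groups need ≥ 20 cells on both sides.
- **Gap-split combinatorial DE test.** Per gene, regions are ordered by
  mean log-normalized expression and split at the largest consecutive gap;
  a Welch t-test on the two groups and one on the two gap-flanking regions
  are combined by max-p / min-log2FC, called at p < 0.05 and LFC > 1
  (0.5 for the neutrophil cross-compartment analysis).
- **Ligand-receptor permutation analysis.** Cell types with ≥ 10 cells in
  every region are balanced to 400 cells/type; the interaction score is the
  average of the ligand's sender-type mean and the receptor's
  receiver-type mean; cell-type labels are shuffled (one shared shuffle per
  permutation) for the null; p = 0 interactions are significant, and an
  interaction is *unique* to a region when significant there while every
  other region's p exceeds 0.95.
- **Supporting steps.** Tissue-class-specific QC (mito ≤ 0.2/0.3/0.6, UMI
  bounds, ≥ 10-cell gene support, doublet score ≤ 0.1), cluster-based size
  factors with log1p normalization, per-sample highly-variable-gene
  selection (bin-normalized dispersion), region dendrograms on 50 averaged
  principal components, gene-set inflammation scores, subgroup-relative
  proportion correlation.
- **Synthetic cohorts with planted truth.** A negative-binomial simulator
  (lognormal gene baselines and library sizes, marker genes, mitochondrial
  share, doublets) with planted region×cell-type×condition expression
  effects and planted ligand-receptor elevations, used throughout the test
  suite for calibration and power checks.

The central container is `MarrowCohort`, an S4 class extending
`SingleCellExperiment` (genes × cells), validated for integer counts and
consistent derived annotations.

## Worked example

```r
library(MarrowDivergence)

cfg <- simConfig(regions = c("calvaria", "femur", "humerus"),
                 cells_per_sample = 200, n_genes = 500, seed = 42)
eff <- plantedEffects(sprintf("g%04d", 101:130), "calvaria", log2_fold = 2)
coh <- simulateCohort(cfg, eff)$cohort

coh <- logNormalize(coh, computeSizeFactors(coh, clusterForSizeFactors(coh)))
divergenceScan(coh, n_perm = 1000, seed = 1)
```

```
  cell_type   region      score n_in n_out n_perm k perm_p significant
1       all calvaria 0.08186388  200   400   1000 0      0        TRUE
2       all    femur 0.02175608  200   400   1000 0      0        TRUE
3       all  humerus 0.02219147  200   400   1000 0      0        TRUE
```

The planted 30-gene calvaria shift dominates: the calvaria explains ~8% of
eigenvalue-weighted PCA variance against the other bones, four times the
score of either unshifted bone, and no permuted labeling reaches it
(k = 0). Note that femur and humerus also test significant: once one bone
truly diverges, every one-vs-rest contrast carries signal, because the
"rest" group of an unshifted bone contains the divergent calvaria. On a
fully null cohort all permutation p-values are uniform (the test suite
verifies this calibration). The same cohort can then be pushed
through `runCombinatorialDE()` (the calvaria genes return with
`high_group == "calvaria"`), `lrAnalysis()` + `callCommonAndUnique()`, and
`regionDendrogram()`; `runPipeline(runConfig(...))` chains all stages with
one global seed and writes deterministic TSVs plus a checksum manifest. A
thin command-line wrapper lives at `inst/scripts/marrow-pipeline.R`.

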