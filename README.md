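# scTMEstats

Downstream statistics for multi-sample tumor/normal single-cell RNA-seq
atlases of the tumor microenvironment (TME) — for analysts who have a
sparse UMI count matrix, per-cell sample/condition/cell-type annotations,
and want the bespoke statistics these studies are built on rather than
another end-to-end framework.

## What it computes

* **QC / normalization / embedding** — cells kept with 200–7,000 expressed
  genes and mitochondrial fraction ≤ 10%; depth normalization to 10,000
  counts with log1p; variable genes by the mean ∈ [0.05, 5], dispersion
  ≥ 0.5 window; covariate regression, scaling (clipped at |10|) and
  20-component PCA.
* **Two-round reclustering** — Leiden clustering on a kNN graph, then a
  per-gene additive two-way ANOVA `expression ~ sample + cluster`
  (type-II sums of squares). Genes whose sample-variance fraction
  `SS_sample / (SS_sample + SS_cluster)` exceeds 0.9 are removed as
  batch-driven and the clustering is redone on the remaining variable
  genes.
* **Cluster robustness** — resample 75% of cells 30 times, recluster, and
  average each cluster's largest single-cluster overlap fraction.
* **Signature genes** — cluster specificity (high-expressed cells above
  the within-cluster first quartile of nonzero expression) and cell-type
  specificity (expressed cells above the global 5th percentile), each
  `max(0, 1 − max_other/f_focal)`, combined by geometric mean with an
  inclusive 0.7 cutoff; Wilcoxon DE test with the expression-percent
  > 10%, fold-change > 2, BH-adjusted p < 0.05 filter; gene-set scores
  (e.g. the exhaustion set PDCD1, LAG3, TIGIT, HAVCR2, CTLA4).
* **Cluster abundance** — per-cluster Poisson GLM of per-sample cell
  counts, `log E[count] = β0 + β1·I(tumor) + log(total)`, Wald test on
  the log rate ratio β1.
* **Dendrogram** — cluster mean-expression profiles, distance
  `(1 − Pearson r)/2`, UPGMA (or NJ) tree, Newick output via `ape`.
* **Ligand-receptor interactions** — CellPhoneDB-style permutation test:
  >25% detection filter per subunit, minimum-subunit rule for complexes,
  mean-of-means statistic, shared label permutations, add-one empirical
  P, directed interaction-count matrix.
* **Bulk validation** — TPM normalization by normal-sample gene means and
  top/bottom-quartile grouping of tumor samples by signature average.
* **Synthetic data with ground truth** — a negative-binomial generator
  with planted cluster markers, batch genes, condition-dependent
  abundances and active ligand-receptor pairs, so every stage above is
  testable without any external download.

## Worked example

```r
library(scTMEstats)

cfg <- simulation_config(
  n_genes = 1000, n_cells_per_sample = 100, n_samples = 6, n_clusters = 3,
  cluster_proportions = list(tumor  = c(0.5, 0.3, 0.2),
                             normal = c(0.2, 0.3, 0.5)),
  n_batch_genes = 13, seed = 42)
sim <- simulate_counts(cfg)

qc   <- qc_filter(sim$counts, sim$cells, qc_thresholds())
norm <- normalize_counts(qc$counts)
vg   <- select_variable_genes(norm)
cat("cells kept:", ncol(qc$counts), "of", ncol(sim$counts),
    "| variable genes:", length(vg), "\n")

res <- two_round_recluster(norm, vg, qc$cells$sample,
                           resolution = 0.4, seed = 1)
cat("round-1 clusters:", length(unique(res$labels_round1)),
    "| round-2 clusters:", length(unique(res$labels)),
    "| sample-driven genes removed:", sum(res$filter$removed), "\n")
cat("ARI vs truth, round 1:",
    round(mclust::adjustedRandIndex(res$labels_round1, qc$cells$true_cluster), 3),
    "round 2:", round(mclust::adjustedRandIndex(res$labels, qc$cells$true_cluster), 3), "\n")

tab <- tabulate_abundance(data.frame(sample = qc$cells$sample,
                                     condition = qc$cells$condition,
                                     cluster = res$labels))
ab <- test_cluster_abundance(tab)
print(ab[, c("cluster", "beta", "z", "p", "direction")], digits = 3)
```

This prints:

```
cells kept: 560 of 600 | variable genes: 688
round-1 clusters: 2 | round-2 clusters: 3 | sample-driven genes removed: 317
ARI vs truth, round 1: 0.477 round 2: 0.906
  cluster  beta      z        p direction
1       1  1.10  6.535 6.36e-11     tumor
2       2 -1.04 -6.329 2.47e-10    normal
3       3 -0.05 -0.335 7.37e-01    normal
```

Read: the 13 planted batch genes (strong per-sample effects) corrupt the
first-round clustering into 2 clusters that half-track samples (adjusted
Rand index 0.48 against the planted truth); the ANOVA filter removes the
sample-driven variable genes, after which round 2 recovers all 3 planted
clusters (ARI 0.91). The abundance GLM then finds one cluster enriched in
tumor samples (log rate ratio 1.10, Wald p ≈ 6e-11) and one in normal
tissue, exactly as planted (tumor proportions 0.5/0.3/0.2 versus normal
0.2/0.3/0.5), while the unshifted cluster is correctly non-significant.

See the vignette (`vignettes/tme-downstream-statistics.Rmd`) for the full
model descriptions, parameter meanings, and the generator's assumptions.

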