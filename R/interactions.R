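#' Detection filter for ligand-receptor pair / cluster-pair combinations
#'
#' A directed combination (pair, sender A, receiver B) is tested only when
#' every ligand subunit is detected (count or normalized value > 0) in more
#' than `min_frac` of cluster-A cells and every receptor subunit in more
#' than `min_frac` of cluster-B cells; a subunit at exactly `min_frac` is
#' excluded. Genes absent from the matrix are treated as undetected.
#'
#' @param norm Log-normalized (or count) genes x cells matrix.
#' @param labels Per-cell cluster labels.
#' @param lr Pair table: data.frame with columns `pair_id`, `ligand_genes`,
#'   `receptor_genes` (subunits semicolon-joined).
#' @param min_frac Detection-fraction threshold (default 0.25, exclusive).
#' @return Data frame with one row per (pair_id, cluster_a, cluster_b)
#'   combination and a logical `tested` column.
#' @export
expression_filter <- function(norm, labels, lr, min_frac = 0.25) {
  if (anyDuplicated(lr$pair_id)) stop("duplicate pair IDs")
  clusters <- sort(unique(labels))
  genes <- unique(unlist(strsplit(
    c(lr$ligand_genes, lr$receptor_genes), ";", fixed = TRUE)))
  present <- intersect(genes, rownames(norm))
  # detection fraction per (gene, cluster)
  det <- matrix(0, length(genes), length(clusters),
                dimnames = list(genes, as.character(clusters)))
  if (length(present)) {
    m <- norm[present, , drop = FALSE] > 0
    for (ci in seq_along(clusters)) {
      det[present, ci] <- Matrix::rowMeans(m[, labels == clusters[ci],
                                             drop = FALSE])
    }
  }
  combos <- expand.grid(pair_id = lr$pair_id, cluster_a = clusters,
                        cluster_b = clusters, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
  combos <- combos[combos$cluster_a != combos$cluster_b, , drop = FALSE]
  lig <- strsplit(lr$ligand_genes[match(combos$pair_id, lr$pair_id)], ";",
                  fixed = TRUE)
  rec <- strsplit(lr$receptor_genes[match(combos$pair_id, lr$pair_id)], ";",
                  fixed = TRUE)
  combos$tested <- vapply(seq_len(nrow(combos)), function(i) {
    all(det[lig[[i]], as.character(combos$cluster_a[i])] > min_frac) &&
      all(det[rec[[i]], as.character(combos$cluster_b[i])] > min_frac)
  }, logical(1))
  rownames(combos) <- NULL
  combos
}

# Mean expression of every LR gene in every cluster for one labeling; the
# minimum-subunit rule and the pair statistic are applied on top of this.
.cluster_gene_means <- function(y, labels, clusters) {
  out <- matrix(NA_real_, nrow(y), length(clusters),
                dimnames = list(rownames(y), as.character(clusters)))
  for (ci in seq_along(clusters)) {
    out[, ci] <- rowMeans(y[, labels == clusters[ci], drop = FALSE])
  }
  out
}

.pair_stat <- function(means, lig, rec, a, b) {
  l <- min(means[lig, a])   # multi-subunit complex: minimum-mean subunit
  r <- min(means[rec, b])
  (l + r) / 2
}

#' Observed ligand-receptor interaction statistic
#'
#' The statistic for (pair, sender A, receiver B) is the mean of the ligand
#' value and the receptor value, where the ligand value is the mean
#' normalized expression of the ligand gene in cluster A (for complexes, the
#' subunit with the minimum cluster-A mean) and the receptor value is the
#' analogous quantity in cluster B.
#'
#' @param norm Log-normalized genes x cells matrix.
#' @param labels Per-cell cluster labels.
#' @param ligand_genes,receptor_genes Character vectors of subunit gene IDs.
#' @param cluster_a Sender cluster; @param cluster_b receiver cluster.
#' @return The interaction statistic (a number).
#' @export
interaction_statistic <- function(norm, labels, ligand_genes, receptor_genes,
                                  cluster_a, cluster_b) {
  y <- as.matrix(norm[unique(c(ligand_genes, receptor_genes)), , drop = FALSE])
  clusters <- sort(unique(labels))
  means <- .cluster_gene_means(y, labels, clusters)
  .pair_stat(means, ligand_genes, receptor_genes,
             as.character(cluster_a), as.character(cluster_b))
}

#' Ligand-receptor permutation test across all cluster pairs
#'
#' For every combination passing the detection filter, compares the observed
#' interaction statistic with its null distribution under `n_perm` random
#' permutations of the cluster labels over all cells. One shared permutation
#' stream is used for every combination (the same label shuffles feed every
#' pair). The empirical P value is one-sided (greater):
#' `(1 + #\{perm >= observed\}) / (n_perm + 1)` by default, so it is never 0;
#' `add_one = FALSE` gives the raw proportion. The count matrix tallies, per
#' directed (sender, receiver) cluster pair, the combinations with empirical
#' P below `alpha`.
#'
#' @param norm Log-normalized genes x cells matrix.
#' @param labels Per-cell cluster labels.
#' @param lr Pair table (`pair_id`, `ligand_genes`, `receptor_genes`;
#'   subunits semicolon-joined).
#' @param n_perm Number of permutations (default 1000; < 100 warns).
#' @param min_frac Detection threshold passed to [expression_filter()].
#' @param alpha Significance threshold for the count matrix (default 0.05).
#' @param add_one Use the add-one empirical P (default TRUE).
#' @param seed Integer seed for the permutation stream.
#' @return List with `results` (data.frame: pair_id, cluster_a, cluster_b,
#'   tested, observed_stat, empirical_p) and `counts` (directed cluster x
#'   cluster matrix of significant combinations).
#' @export
permutation_test <- function(norm, labels, lr, n_perm = 1000L,
                             min_frac = 0.25, alpha = 0.05, add_one = TRUE,
                             seed = 1L) {
  clusters <- sort(unique(labels))
  if (length(clusters) < 2) stop("need at least 2 clusters")
  if (n_perm < 100) warning("n_perm < 100 gives a coarse empirical P value")
  combos <- expression_filter(norm, labels, lr, min_frac)
  combos$observed_stat <- rep(NA_real_, nrow(combos))
  combos$empirical_p <- rep(NA_real_, nrow(combos))
  counts <- matrix(0L, length(clusters), length(clusters),
                   dimnames = list(sender = as.character(clusters),
                                   receiver = as.character(clusters)))
  tested <- which(combos$tested)
  if (length(tested) == 0 || nrow(lr) == 0) {
    return(list(results = combos, counts = counts))
  }
  lig <- strsplit(lr$ligand_genes[match(combos$pair_id, lr$pair_id)], ";",
                  fixed = TRUE)
  rec <- strsplit(lr$receptor_genes[match(combos$pair_id, lr$pair_id)], ";",
                  fixed = TRUE)
  need <- unique(unlist(c(lig[tested], rec[tested])))
  y <- as.matrix(norm[need, , drop = FALSE])
  obs_means <- .cluster_gene_means(y, labels, clusters)
  obs <- vapply(tested, function(i) {
    .pair_stat(obs_means, lig[[i]], rec[[i]],
               as.character(combos$cluster_a[i]),
               as.character(combos$cluster_b[i]))
  }, numeric(1))
  exceed <- integer(length(tested))
  set.seed(seed)
  for (p in seq_len(n_perm)) {
    perm <- sample(labels)
    pm <- .cluster_gene_means(y, perm, clusters)
    ps <- vapply(tested, function(i) {
      .pair_stat(pm, lig[[i]], rec[[i]],
                 as.character(combos$cluster_a[i]),
                 as.character(combos$cluster_b[i]))
    }, numeric(1))
    exceed <- exceed + (ps >= obs)
  }
  emp <- if (add_one) (1 + exceed) / (n_perm + 1) else exceed / n_perm
  combos$observed_stat[tested] <- obs
  combos$empirical_p[tested] <- emp
  sig <- tested[emp < alpha]
  for (i in sig) {
    a <- as.character(combos$cluster_a[i]); b <- as.character(combos$cluster_b[i])
    counts[a, b] <- counts[a, b] + 1L
  }
  list(results = combos, counts = counts)
}
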