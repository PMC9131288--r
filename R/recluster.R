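#' Graph-based clustering of an embedding
#'
#' Builds an (undirected, unweighted) k-nearest-neighbor graph on the
#' embedding rows and partitions it with Leiden community detection under
#' the modularity objective at the given resolution. Labels are integers
#' 1..k ordered by decreasing cluster size; runs are deterministic under a
#' fixed seed.
#'
#' @param emb Cells x components numeric matrix.
#' @param resolution Modularity resolution (> 0); higher gives more, smaller
#'   clusters.
#' @param n_neighbors Neighbors per cell for the kNN graph (default 20).
#' @param seed Integer seed for the community-detection refinement.
#' @return Integer vector of cluster labels, one per row of `emb`.
#' @export
graph_cluster <- function(emb, resolution = 0.4, n_neighbors = 20L, seed = 0L) {
  n <- nrow(emb)
  if (resolution <= 0) stop("resolution must be > 0")
  if (n < n_neighbors + 1) stop("fewer cells than n_neighbors + 1")
  d <- as.matrix(stats::dist(emb))
  nn <- apply(d, 1L, function(r) order(r)[2:(n_neighbors + 1L)])
  edges <- cbind(rep(seq_len(n), each = n_neighbors), as.vector(nn))
  g <- igraph::simplify(igraph::graph_from_edgelist(edges, directed = FALSE))
  set.seed(seed)
  cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = resolution, n_iterations = 5L)
  memb <- as.integer(igraph::membership(cl))
  sizes <- sort(table(memb), decreasing = TRUE)
  relab <- stats::setNames(seq_along(sizes), names(sizes))
  unname(relab[as.character(memb)])
}

#' Two-way ANOVA partition of gene variance into sample and cluster parts
#'
#' Fits, per gene, the additive two-factor linear model
#' `expression ~ sample + cluster` on per-cell values and computes type-II
#' sums of squares for each factor (`SS_sample = RSS(cluster) - RSS(full)`,
#' `SS_cluster = RSS(sample) - RSS(full)`; invariant to factor order in the
#' additive model). The sample-variance fraction is
#' `SS_sample / (SS_sample + SS_cluster)`; genes above `threshold` are
#' flagged for removal as sample-driven (batch) genes. A constant gene has
#' both sums of squares zero; its fraction is defined as 0 and it is never
#' removed.
#'
#' @param norm Log-normalized genes x cells matrix (restrict via `genes`).
#' @param sample_ids Per-cell sample factor (>= 2 levels).
#' @param cluster_labels Per-cell cluster factor (>= 2 levels).
#' @param genes Genes to test (default: all rows, typically the variable
#'   genes).
#' @param threshold Removal threshold on the sample fraction (default 0.9).
#' @param type Sums-of-squares type, `"II"` (default) or `"I"` (sequential,
#'   sample first).
#' @return Data frame: gene, ss_sample, ss_cluster, sample_fraction, removed.
#' @export
anova_gene_filter <- function(norm, sample_ids, cluster_labels,
                              genes = rownames(norm), threshold = 0.9,
                              type = c("II", "I")) {
  type <- match.arg(type)
  s <- droplevels(factor(sample_ids))
  k <- droplevels(factor(cluster_labels))
  if (nlevels(s) < 2) stop("need at least 2 samples")
  if (nlevels(k) < 2) stop("need at least 2 clusters")
  y <- t(as.matrix(norm[genes, , drop = FALSE]))   # cells x genes
  if (any(!is.finite(y))) stop("non-finite expression values")
  rss <- function(x) {
    q <- qr(x)
    fitted_ss <- colSums(qr.qty(q, y)[seq_len(q$rank), , drop = FALSE]^2)
    pmax(colSums(y^2) - fitted_ss, 0)
  }
  rss_full <- rss(stats::model.matrix(~ s + k))
  rss_s <- rss(stats::model.matrix(~ s))
  rss_k <- rss(stats::model.matrix(~ k))
  if (type == "II") {
    ss_sample <- pmax(rss_k - rss_full, 0)
    ss_cluster <- pmax(rss_s - rss_full, 0)
  } else {
    rss_0 <- rss(matrix(1, nrow(y), 1))
    ss_sample <- pmax(rss_0 - rss_s, 0)
    ss_cluster <- pmax(rss_s - rss_full, 0)
  }
  denom <- ss_sample + ss_cluster
  frac <- ifelse(denom > 1e-12, ss_sample / denom, 0)
  data.frame(gene = genes, ss_sample = ss_sample, ss_cluster = ss_cluster,
             sample_fraction = frac, removed = frac > threshold,
             row.names = NULL)
}

#' Two-round reclustering with removal of sample-driven variable genes
#'
#' Round 1 embeds and clusters on the full variable-gene set; the two-way
#' ANOVA filter (using the round-1 labels) removes variable genes whose
#' expression variance is mainly sample-driven; the embedding is recomputed
#' on the surviving genes and round 2 reclusters. The clustering resolution
#' is a user choice (typically tried at 0.4, 0.6 and 0.8) recorded in the
#' output metadata, never auto-selected.
#'
#' @param norm Log-normalized genes x cells matrix.
#' @param var_genes Variable genes for round 1.
#' @param sample_ids Per-cell sample IDs.
#' @param resolution,n_neighbors,seed Clustering parameters, shared by both
#'   rounds (see [graph_cluster()]).
#' @param covariates,n_components Passed to [regress_and_embed()].
#' @param threshold ANOVA sample-fraction removal threshold (default 0.9).
#' @return List: `labels` (round 2), `labels_round1`, `filter` (the
#'   [anova_gene_filter()] table), `genes_used` (round-2 gene set), `params`.
#' @export
two_round_recluster <- function(norm, var_genes, sample_ids,
                                resolution = 0.4, n_neighbors = 20L,
                                seed = 0L, covariates = NULL,
                                n_components = 20L, threshold = 0.9) {
  emb1 <- regress_and_embed(norm, var_genes, covariates, n_components)
  lab1 <- graph_cluster(emb1, resolution, n_neighbors, seed)
  if (length(unique(lab1)) < 2)
    stop("round-1 clustering produced a single cluster; ",
         "raise the resolution or check the variable-gene set")
  flt <- anova_gene_filter(norm, sample_ids, lab1, genes = var_genes,
                           threshold = threshold)
  kept <- flt$gene[!flt$removed]
  if (length(kept) < 2) {
    stop(errorCondition(
      "all variable genes removed by the sample-variance filter",
      filter = flt, class = c("anova_filter_error", "error", "condition")))
  }
  emb2 <- regress_and_embed(norm, kept, covariates, n_components)
  lab2 <- graph_cluster(emb2, resolution, n_neighbors, seed)
  list(labels = lab2, labels_round1 = lab1, filter = flt, genes_used = kept,
       params = list(resolution = resolution, n_neighbors = n_neighbors,
                     seed = seed, threshold = threshold))
}

#' Cluster robustness by resampling
#'
#' Repeatedly samples a fraction of cells without replacement, reclusters
#' them with identical parameters on the same embedding features, and
#' records for each original cluster the largest fraction of its sampled
#' members assigned to a single resampled cluster. Robustness is the mean of
#' that fraction over repetitions; a cluster with no sampled members in a
#' repetition is skipped for that repetition.
#'
#' @param emb Cells x components embedding the labels were computed on.
#' @param labels Original cluster labels.
#' @param resolution,n_neighbors Clustering parameters, identical to those
#'   that produced `labels`.
#' @param n_rep Number of resampling repetitions (default 30).
#' @param frac Fraction of cells sampled each repetition (default 0.75).
#' @param seed Integer seed for the whole procedure.
#' @return Data frame: cluster, robustness, n_reps_used.
#' @export
cluster_robustness <- function(emb, labels, resolution = 0.4,
                               n_neighbors = 20L, n_rep = 30L, frac = 0.75,
                               seed = 0L) {
  n <- nrow(emb)
  stopifnot(length(labels) == n)
  clusters <- sort(unique(labels))
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_rep)
  res <- matrix(NA_real_, n_rep, length(clusters),
                dimnames = list(NULL, as.character(clusters)))
  for (r in seq_len(n_rep)) {
    idx <- sort(sample.int(n, floor(frac * n)))
    sub <- graph_cluster(emb[idx, , drop = FALSE], resolution, n_neighbors,
                         seed = rep_seeds[r])
    orig <- labels[idx]
    for (ci in seq_along(clusters)) {
      members <- which(orig == clusters[ci])
      if (length(members) == 0) next
      res[r, ci] <- max(table(sub[members])) / length(members)
    }
  }
  data.frame(cluster = clusters,
             robustness = colMeans(res, na.rm = TRUE),
             n_reps_used = colSums(!is.na(res)),
             row.names = NULL)
}
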