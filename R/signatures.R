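# Shared helper: fraction of cells per group whose value exceeds t.
.frac_above <- function(values, groups, t) {
  vapply(split(values > t, groups), mean, numeric(1))
}

#' Cluster specificity score of a gene for a focal cluster
#'
#' "High-expressed" cells are those whose expression exceeds the first
#' quartile of the gene's nonzero values within the focal cluster. With
#' `h_c` the fraction of high-expressed cells in cluster `c`, the score is
#' `max(0, 1 - max_{c != focal}(h_c) / h_focal)`: 1 when the gene is
#' expressed exclusively in the focal cluster, 0 when any other cluster's
#' high-expressed fraction equals or exceeds the focal fraction. A gene with
#' no nonzero value in the focal cluster scores 0. The score depends only on
#' ranks against a within-data quantile, so it is invariant to monotone
#' rescaling of the expression values.
#'
#' @param norm Log-normalized genes x cells matrix, restricted to the cells
#'   of one cell type.
#' @param labels Per-cell cluster labels within that cell type.
#' @param gene Gene ID.
#' @param focal_cluster Cluster the score is computed for.
#' @param quantile_prob Quantile defining "high expressed" (default 0.25).
#' @return A number in \[0, 1\].
#' @export
cluster_specificity <- function(norm, labels, gene, focal_cluster,
                                quantile_prob = 0.25) {
  if (!focal_cluster %in% labels) stop("unknown cluster: ", focal_cluster)
  if (length(unique(labels)) < 2) {
    warning("only one cluster present; cluster specificity defined as 1")
    return(1)
  }
  x <- as.numeric(norm[gene, ])
  focal_vals <- x[labels == focal_cluster]
  nz <- focal_vals[focal_vals > 0]
  if (length(nz) == 0) return(0)
  t <- stats::quantile(nz, quantile_prob, names = FALSE)
  h <- .frac_above(x, labels, t)
  h_focal <- h[as.character(focal_cluster)]
  if (h_focal == 0) return(0)
  h_other <- h[names(h) != as.character(focal_cluster)]
  max(0, 1 - max(h_other) / h_focal)
}

#' Cell type specificity score of a gene for a focal cell type
#'
#' A cell is "expressed" when its value exceeds the 5th percentile of the
#' gene's nonzero values over all cells (all types pooled). With `f_T` the
#' expressed fraction within each type, the score is
#' `max(0, 1 - max_{T != focal}(f_T) / f_focal)`; zero focal expression
#' gives 0. With a single cell type present the score is defined as 1, with
#' a warning.
#'
#' @param norm Log-normalized genes x cells matrix over all cell types.
#' @param type_labels Per-cell major cell type labels.
#' @param gene Gene ID.
#' @param focal_type Cell type the score is computed for.
#' @param quantile_prob Percentile defining "expressed" (default 0.05).
#' @return A number in \[0, 1\].
#' @export
cell_type_specificity <- function(norm, type_labels, gene, focal_type,
                                  quantile_prob = 0.05) {
  types <- unique(type_labels)
  if (!focal_type %in% types) stop("unknown cell type: ", focal_type)
  if (length(types) < 2) {
    warning("only one cell type present; cell type specificity defined as 1")
    return(1)
  }
  x <- as.numeric(norm[gene, ])
  nz <- x[x > 0]
  if (length(nz) == 0) return(0)
  t <- stats::quantile(nz, quantile_prob, names = FALSE)
  f <- .frac_above(x, type_labels, t)
  f_focal <- f[as.character(focal_type)]
  if (f_focal == 0) return(0)
  f_other <- f[names(f) != as.character(focal_type)]
  max(0, 1 - max(f_other) / f_focal)
}

#' Identify signature genes by combined specificity score
#'
#' For each candidate (gene, cluster) pair — typically the cluster's
#' differentially expressed genes — computes the cluster specificity score
#' (within the cluster's cell type) and the cell type specificity score
#' (across all cells), combines them by geometric mean, and flags genes
#' whose combined score reaches the cutoff. Output is sorted by combined
#' score descending, ties broken by gene ID.
#'
#' @param norm Log-normalized genes x cells matrix over all cell types.
#' @param cluster_labels Per-cell cluster labels.
#' @param type_labels Per-cell major cell type labels; each cluster must lie
#'   within one cell type (the majority type is used otherwise).
#' @param candidates Data frame with columns `gene` and `cluster`.
#' @param cutoff Signature cutoff on the combined score, inclusive
#'   (default 0.7).
#' @return Data frame: gene, cluster, cluster_specificity,
#'   cell_type_specificity, combined, is_signature.
#' @export
identify_signature_genes <- function(norm, cluster_labels, type_labels,
                                     candidates, cutoff = 0.7) {
  stopifnot(all(c("gene", "cluster") %in% names(candidates)))
  type_of_cluster <- function(cl) {
    tt <- table(type_labels[cluster_labels == cl])
    names(tt)[which.max(tt)]
  }
  n <- nrow(candidates)
  cs <- numeric(n); cts <- numeric(n)
  for (i in seq_len(n)) {
    g <- candidates$gene[i]; cl <- candidates$cluster[i]
    ft <- type_of_cluster(cl)
    in_type <- type_labels == ft
    cs[i] <- suppressWarnings(
      cluster_specificity(norm[, in_type, drop = FALSE],
                          cluster_labels[in_type], g, cl))
    cts[i] <- suppressWarnings(
      cell_type_specificity(norm, type_labels, g, ft))
  }
  out <- data.frame(gene = candidates$gene, cluster = candidates$cluster,
                    cluster_specificity = cs, cell_type_specificity = cts,
                    combined = sqrt(cs * cts), row.names = NULL)
  out$is_signature <- out$combined >= cutoff
  out[order(-out$combined, out$gene), , drop = FALSE]
}

#' Mean expression of a gene set per cell (or per bulk sample)
#'
#' Arithmetic mean of normalized expression over the set genes present in
#' the matrix, e.g. the exhaustion score over PDCD1, LAG3, TIGIT, HAVCR2 and
#' CTLA4, or an M1/M2 macrophage signature. Missing genes are reported via
#' the `"missing_genes"` attribute; if fewer than `min_coverage` of the set
#' is present the call errors, naming the missing genes.
#'
#' @param norm Log-normalized genes x cells (or genes x samples) matrix.
#' @param gene_set Character vector of gene IDs.
#' @param min_coverage Minimum fraction of the set that must be present
#'   (default 0.5).
#' @return Numeric vector of per-column scores with attributes
#'   `"missing_genes"` and `"genes_used"`.
#' @export
gene_set_score <- function(norm, gene_set, min_coverage = 0.5) {
  gene_set <- unique(gene_set)
  present <- intersect(gene_set, rownames(norm))
  missing <- setdiff(gene_set, present)
  if (length(present) < min_coverage * length(gene_set)) {
    stop("gene set coverage below ", min_coverage, "; missing: ",
         paste(missing, collapse = ", "))
  }
  score <- Matrix::colMeans(norm[present, , drop = FALSE])
  score <- stats::setNames(as.numeric(score), colnames(norm))
  attr(score, "missing_genes") <- missing
  attr(score, "genes_used") <- present
  score
}

# Two-sided Wilcoxon rank-sum p-values (normal approximation with tie and
# continuity corrections), one test per matrix row; the first `na` columns
# of y must be group A.
.ranksum_p <- function(y, na, nb) {
  apply(y, 1L, function(v) {
    r <- rank(v)
    w <- sum(r[seq_len(na)]) - na * (na + 1) / 2
    mu <- na * nb / 2
    ties <- table(v)
    sigma2 <- na * nb / 12 *
      ((na + nb + 1) - sum(ties^3 - ties) / ((na + nb) * (na + nb - 1)))
    if (sigma2 <= 0) return(1)
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    min(1, 2 * stats::pnorm(-abs(z)))
  })
}

#' Differential expression between two cell groups
#'
#' Per-gene two-sided Wilcoxon rank-sum test on log-normalized values with
#' Benjamini-Hochberg adjustment across the tested genes. Fold change is the
#' ratio of depth-scaled group means with pseudocount 1,
#' `(mean(expm1(a)) + 1) / (mean(expm1(b)) + 1)`. Expression percent is the
#' fraction of cells with nonzero expression per group. A gene passes the
#' filter when its expression percent exceeds `min_pct` in at least one
#' group, its fold change exceeds `min_fc`, and its adjusted p is below
#' `alpha`.
#'
#' @param norm Log-normalized genes x cells matrix.
#' @param cells_a,cells_b Column indices (or logical/character selectors) of
#'   the two groups; each must contain at least 3 cells.
#' @param min_pct Expression-percent threshold (default 0.10, exclusive).
#' @param min_fc Fold-change threshold, group A over group B (default 2,
#'   exclusive).
#' @param alpha Adjusted-p threshold (default 0.05, exclusive).
#' @return Data frame: gene, fold_change, log2_fold_change, pct_a, pct_b, p,
#'   p_adj, passes_filter.
#' @export
de_test <- function(norm, cells_a, cells_b, min_pct = 0.10, min_fc = 2,
                    alpha = 0.05) {
  a <- as.matrix(norm[, cells_a, drop = FALSE])
  b <- as.matrix(norm[, cells_b, drop = FALSE])
  if (ncol(a) < 3 || ncol(b) < 3) stop("both groups need at least 3 cells")
  y <- cbind(a, b)
  p <- .ranksum_p(y, ncol(a), ncol(b))
  mean_a <- rowMeans(expm1(a)); mean_b <- rowMeans(expm1(b))
  fc <- (mean_a + 1) / (mean_b + 1)
  pct_a <- rowMeans(a > 0); pct_b <- rowMeans(b > 0)
  p_adj <- stats::p.adjust(p, "BH")
  data.frame(gene = rownames(norm), fold_change = fc,
             log2_fold_change = log2(fc), pct_a = pct_a, pct_b = pct_b,
             p = p, p_adj = p_adj,
             passes_filter = (pmax(pct_a, pct_b) > min_pct) & fc > min_fc &
               p_adj < alpha,
             row.names = NULL)
}
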