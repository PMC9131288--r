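#' Mean expression profile per cluster
#'
#' @param norm Log-normalized genes x cells matrix.
#' @param labels Per-cell cluster labels.
#' @param genes Genes to profile (default: all; typically the variable genes
#'   surviving the sample-variance filter for the cell type).
#' @return Clusters x genes matrix of mean normalized expression.
#' @export
cluster_profiles <- function(norm, labels, genes = rownames(norm)) {
  y <- t(as.matrix(norm[genes, , drop = FALSE]))
  f <- factor(labels)
  rowsum(y, f) / as.vector(table(f))
}

#' Correlation distance between cluster profiles
#'
#' Distance between two clusters is `(1 - Pearson r) / 2` of their mean
#' expression profiles across genes, so identical profiles are at distance 0
#' and perfectly anticorrelated profiles at distance 1.
#'
#' @param profiles Clusters x genes matrix from [cluster_profiles()].
#' @return Symmetric clusters x clusters distance matrix with zero diagonal.
#' @export
cluster_distance <- function(profiles) {
  if (nrow(profiles) < 2) stop("need at least 2 clusters")
  if (ncol(profiles) < 2) stop("need at least 2 genes")
  sds <- apply(profiles, 1L, stats::sd)
  if (any(sds == 0))
    stop("constant expression profile for cluster(s): ",
         paste(rownames(profiles)[sds == 0], collapse = ", "))
  r <- stats::cor(t(profiles))
  d <- (1 - r) / 2
  diag(d) <- 0
  d
}

#' Build a cluster dendrogram from a correlation distance matrix
#'
#' Agglomerates by average linkage (UPGMA, default) or neighbor joining;
#' returns an `ape::phylo` tree whose leaves are the cluster names, ready to
#' be serialized as Newick with [ape::write.tree()].
#'
#' @param dist Symmetric distance matrix from [cluster_distance()].
#' @param method `"average"` (UPGMA) or `"nj"`.
#' @return An object of class `phylo`.
#' @export
build_tree <- function(dist, method = c("average", "nj")) {
  method <- match.arg(method)
  if (!isSymmetric(unname(as.matrix(dist)), tol = 1e-8))
    stop("distance matrix must be symmetric")
  d <- stats::as.dist(dist)
  if (method == "nj") {
    ape::nj(d)
  } else {
    ape::as.phylo(stats::hclust(d, method = "average"))
  }
}
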