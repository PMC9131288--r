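# Independent oracles and small fixture builders shared across tests.

# Dense genes x cells matrix -> sparse, with default dimnames.
as_norm <- function(m, genes = NULL, cells = NULL) {
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(m)))
  if (is.null(cells)) cells <- sprintf("c%03d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, cells)
  methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE),
                          "generalMatrix"), "CsparseMatrix")
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Direct transcription of the cluster-specificity definition, written with
# explicit loops and no shared code with the implementation.
oracle_cluster_specificity <- function(mat, labels, gene, focal) {
  x <- as.numeric(mat[gene, ])
  focal_nz <- x[labels == focal & x > 0]
  if (length(focal_nz) == 0) return(0)
  t <- as.numeric(quantile(focal_nz, 0.25))
  cls <- unique(labels)
  h <- numeric(length(cls)); names(h) <- as.character(cls)
  for (cl in cls) {
    v <- x[labels == cl]
    h[as.character(cl)] <- sum(v > t) / length(v)
  }
  hf <- h[as.character(focal)]
  if (hf == 0) return(0)
  ho <- max(h[names(h) != as.character(focal)])
  max(0, 1 - ho / hf)
}

oracle_cell_type_specificity <- function(mat, types, gene, focal) {
  x <- as.numeric(mat[gene, ])
  nz <- x[x > 0]
  if (length(nz) == 0) return(0)
  t <- as.numeric(quantile(nz, 0.05))
  tys <- unique(types)
  f <- numeric(length(tys)); names(f) <- as.character(tys)
  for (ty in tys) {
    v <- x[types == ty]
    f[as.character(ty)] <- sum(v > t) / length(v)
  }
  ff <- f[as.character(focal)]
  if (ff == 0) return(0)
  fo <- max(f[names(f) != as.character(focal)])
  max(0, 1 - fo / ff)
}

# On a balanced sample x cluster grid the additive design is orthogonal, so
# the per-factor sums of squares follow directly from group means.
oracle_balanced_anova_fraction <- function(values, samples, clusters) {
  grand <- mean(values)
  ss_s <- 0
  for (s in unique(samples)) {
    v <- values[samples == s]
    ss_s <- ss_s + length(v) * (mean(v) - grand)^2
  }
  ss_c <- 0
  for (k in unique(clusters)) {
    v <- values[clusters == k]
    ss_c <- ss_c + length(v) * (mean(v) - grand)^2
  }
  if (ss_s + ss_c < 1e-12) return(0)
  ss_s / (ss_s + ss_c)
}

# Two well-separated Gaussian blobs in a 2-D embedding.
make_blobs <- function(n_per = 60, sep = 50, seed = 42) {
  set.seed(seed)
  emb <- rbind(
    cbind(rnorm(n_per), rnorm(n_per)),
    cbind(rnorm(n_per) + sep, rnorm(n_per))
  )
  list(emb = emb, truth = rep(1:2, each = n_per))
}
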