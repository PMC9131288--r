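#' QC thresholds for cell filtering
#'
#' @param min_genes Cells with fewer expressed genes are removed (a cell with
#'   exactly `min_genes` is retained).
#' @param max_genes Cells with more expressed genes are removed (a cell with
#'   exactly `max_genes` is retained).
#' @param max_mito_fraction Cells whose mitochondrial count fraction exceeds
#'   this value are removed (exactly at the boundary is retained).
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_genes = 200L, max_genes = 7000L,
                          max_mito_fraction = 0.10) {
  if (min_genes >= max_genes) stop("min_genes must be < max_genes")
  if (max_mito_fraction < 0 || max_mito_fraction > 1)
    stop("max_mito_fraction must lie in [0, 1]")
  structure(list(min_genes = min_genes, max_genes = max_genes,
                 max_mito_fraction = max_mito_fraction),
            class = "qc_thresholds")
}

#' Filter cells on expressed-gene count and mitochondrial fraction
#'
#' An "expressed gene" is one with count > 0. Cells are removed when they
#' express fewer than `min_genes` or more than `max_genes` genes, or when
#' their mitochondrial fraction exceeds `max_mito_fraction`; all three
#' boundaries are inclusive for retention. The gene set is unchanged.
#'
#' @param counts Sparse genes x cells count matrix.
#' @param cells Per-cell data.frame aligned with the columns of `counts`.
#' @param thr A [qc_thresholds()] object.
#' @param mito_pattern Regular expression identifying mitochondrial genes in
#'   the rownames (default `"^MT-"`).
#' @return List with filtered `counts` and `cells`; `cells` gains QC metric
#'   columns `n_genes_detected`, `total_umi`, `mito_fraction`.
#' @export
qc_filter <- function(counts, cells, thr = qc_thresholds(),
                      mito_pattern = "^MT-") {
  stopifnot(ncol(counts) == nrow(cells))
  detected <- Matrix::colSums(counts > 0)
  total <- Matrix::colSums(counts)
  mito <- grepl(mito_pattern, rownames(counts))
  mito_frac <- if (any(mito)) {
    as.numeric(Matrix::colSums(counts[mito, , drop = FALSE])) / pmax(total, 1)
  } else rep(0, ncol(counts))
  keep <- detected >= thr$min_genes & detected <= thr$max_genes &
    mito_frac <= thr$max_mito_fraction
  if (!any(keep)) stop("no cells survive QC filtering")
  cells <- cells[keep, , drop = FALSE]
  cells$n_genes_detected <- as.integer(detected[keep])
  cells$total_umi <- as.numeric(total[keep])
  cells$mito_fraction <- mito_frac[keep]
  rownames(cells) <- NULL
  list(counts = counts[, keep, drop = FALSE], cells = cells)
}

#' Log-normalize a UMI count matrix
#'
#' Scales each cell to `scale_factor` total counts and applies `log(1 + x)`:
#' `value(g, c) = log1p(scale_factor * count(g, c) / total(c))`.
#'
#' @param counts Sparse genes x cells count matrix with no zero-total cells.
#' @param scale_factor Per-cell target total (default 10000).
#' @return Sparse genes x cells matrix of log-normalized expression.
#' @export
normalize_counts <- function(counts, scale_factor = 1e4) {
  totals <- Matrix::colSums(counts)
  if (any(totals == 0)) stop("zero-total cells present; run QC first")
  norm <- methods::as(methods::as(counts, "generalMatrix"), "CsparseMatrix")
  norm@x <- log1p(norm@x * rep.int(scale_factor / totals, diff(norm@p)))
  norm
}

#' Select variably expressed genes by mean/dispersion window
#'
#' Mean and dispersion are computed on `expm1` of the log-normalized values
#' (i.e. on the depth-scaled expression). A gene is variable when its mean
#' lies in `[mean_min, mean_max]` and its dispersion (variance / mean) is at
#' least `dispersion_min`.
#'
#' @param norm Log-normalized matrix from [normalize_counts()].
#' @param mean_min,mean_max Inclusive bounds on the mean (defaults 0.05, 5).
#' @param dispersion_min Minimum dispersion (default 0.5).
#' @return Character vector of selected gene IDs; the full per-gene table is
#'   attached as attribute `"stats"`.
#' @export
select_variable_genes <- function(norm, mean_min = 0.05, mean_max = 5,
                                  dispersion_min = 0.5) {
  if (mean_min >= mean_max) stop("mean_min must be < mean_max")
  if (ncol(norm) < 2) stop("need at least 2 cells")
  e <- norm
  e@x <- expm1(e@x)
  n <- ncol(e)
  mu <- Matrix::rowMeans(e)
  e@x <- e@x^2
  ex2 <- Matrix::rowMeans(e)
  v <- (ex2 - mu^2) * n / (n - 1)
  disp <- ifelse(mu > 0, v / mu, 0)
  keep <- mu >= mean_min & mu <= mean_max & disp >= dispersion_min
  out <- rownames(norm)[keep]
  attr(out, "stats") <- data.frame(gene = rownames(norm), mean = mu,
                                   variance = v, dispersion = disp,
                                   variable = keep, row.names = NULL)
  out
}

#' Regress out covariates, scale, and embed by PCA
#'
#' For each selected gene the expression is replaced by the residuals of a
#' linear fit on the covariates, then centered, scaled to unit variance and
#' clipped at `clip`; cells are projected onto the top principal components
#' of the variable genes. When an externally computed embedding (e.g. from a
#' batch-integration tool) is supplied it is returned unchanged, making the
#' downstream clustering contract integration-agnostic.
#'
#' @param norm Log-normalized genes x cells matrix.
#' @param genes Variable genes to embed on.
#' @param covariates Optional per-cell data.frame/matrix of covariates (e.g.
#'   total UMI, mito fraction, cell-cycle scores). Collinear or constant
#'   columns are dropped with a warning.
#' @param n_components Number of principal components (default 20).
#' @param clip Cap on absolute scaled values (default 10).
#' @param external_embedding Optional precomputed cells x components matrix.
#' @return Cells x components numeric matrix with attribute `"sdev"` (the
#'   component standard deviations).
#' @export
regress_and_embed <- function(norm, genes, covariates = NULL,
                              n_components = 20L, clip = 10,
                              external_embedding = NULL) {
  if (!is.null(external_embedding)) {
    stopifnot(nrow(external_embedding) == ncol(norm))
    return(external_embedding)
  }
  genes <- intersect(genes, rownames(norm))
  if (length(genes) < 2) stop("need at least 2 variable genes to embed")
  y <- t(as.matrix(norm[genes, , drop = FALSE]))   # cells x genes
  if (!is.null(covariates)) {
    x <- cbind(`(Intercept)` = 1, as.matrix(covariates))
    qx <- qr(x)
    if (qx$rank < ncol(x)) {
      drop <- colnames(x)[qx$pivot[-seq_len(qx$rank)]]
      warning("dropping collinear covariate column(s): ",
              paste(drop, collapse = ", "))
      x <- x[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
      qx <- qr(x)
    }
    y <- qr.resid(qx, y)
  }
  z <- scale(y)
  z[, attr(z, "scaled:scale") == 0] <- 0
  z[is.na(z)] <- 0
  z <- pmin(pmax(z, -clip), clip)
  k <- min(n_components, ncol(z), nrow(z) - 1L)
  sv <- svd(z, nu = 0, nv = k)
  v <- sv$v
  # deterministic sign: largest-magnitude loading positive
  for (j in seq_len(ncol(v))) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) v[, j] <- -v[, j]
  }
  emb <- z %*% v
  dimnames(emb) <- list(colnames(norm), paste0("PC", seq_len(k)))
  attr(emb, "sdev") <- sv$d[seq_len(k)] / sqrt(max(1, nrow(z) - 1))
  emb
}
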