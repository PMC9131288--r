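#' Write a count matrix as a 10x-style MTX triplet
#'
#' Writes `matrix.mtx`, `features.tsv` (gene IDs) and `barcodes.tsv` into
#' `dir`, uncompressed.
#'
#' @param counts Sparse genes x cells count matrix with dimnames.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_10x <- function(counts, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(methods::as(counts, "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "features.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a 10x-style MTX triplet
#'
#' @param dir Directory containing `matrix.mtx`, `features.tsv`,
#'   `barcodes.tsv`.
#' @return Sparse genes x cells `dgCMatrix` with dimnames.
#' @export
read_10x <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  m <- methods::as(methods::as(m, "generalMatrix"), "CsparseMatrix")
  dimnames(m) <- list(readLines(file.path(dir, "features.tsv")),
                      readLines(file.path(dir, "barcodes.tsv")))
  m
}

#' Read / write the per-cell annotation table
#'
#' Tab-separated with a header (`barcode`, `sample`, `condition`,
#' `cell_type`, ... plus any cluster or QC columns).
#'
#' @param cells Data frame of per-cell annotations.
#' @param path File path.
#' @return `read_cells` returns the data frame; `write_cells` the path,
#'   invisibly.
#' @export
write_cells <- function(cells, path) {
  utils::write.table(cells, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_cells
#' @export
read_cells <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read / write a ligand-receptor pair table
#'
#' Tab-separated with columns `pair_id`, `ligand_genes`, `receptor_genes`;
#' multi-subunit complexes are semicolon-joined within a field.
#'
#' @param lr Pair table data frame.
#' @param path File path.
#' @return `read_lr_pairs` returns the data frame (validated for duplicate
#'   pair IDs); `write_lr_pairs` the path, invisibly.
#' @export
write_lr_pairs <- function(lr, path) {
  utils::write.table(lr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lr_pairs
#' @export
read_lr_pairs <- function(path) {
  lr <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (anyDuplicated(lr$pair_id)) stop("duplicate pair IDs in ", path)
  lr
}

#' Read / write a bulk expression table
#'
#' Tab-separated genes x samples matrix with gene IDs in the first column.
#'
#' @param tpm Genes x samples numeric matrix.
#' @param path File path.
#' @return `read_bulk` returns the matrix; `write_bulk` the path, invisibly.
#' @export
write_bulk <- function(tpm, path) {
  utils::write.table(data.frame(gene = rownames(tpm), tpm,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bulk
#' @export
read_bulk <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  m
}
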