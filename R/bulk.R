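#' Normalize a bulk TPM table by the normal-sample mean
#'
#' Each gene's TPM values are divided by that gene's average TPM over the
#' normal samples, so retained genes have normalized mean exactly 1 across
#' the normal samples. Genes with zero normal mean cannot be normalized and
#' are excluded, reported via the `"excluded_genes"` attribute.
#'
#' @param tpm Genes x samples non-negative TPM matrix.
#' @param labels Per-sample labels, `"tumor"` or `"normal"` (named by sample
#'   or in column order).
#' @return Normalized genes x samples matrix with attribute
#'   `"excluded_genes"`.
#' @export
normalize_bulk <- function(tpm, labels) {
  if (!is.null(names(labels))) labels <- labels[colnames(tpm)]
  if (!any(labels == "normal")) stop("at least one normal sample is required")
  if (any(tpm < 0)) stop("TPM values must be non-negative")
  nm <- rowMeans(tpm[, labels == "normal", drop = FALSE])
  excluded <- rownames(tpm)[nm == 0]
  keep <- nm > 0
  out <- tpm[keep, , drop = FALSE] / nm[keep]
  attr(out, "excluded_genes") <- excluded
  out
}

#' Assign tumor samples to high/low signature-expression quartile groups
#'
#' Computes the per-sample mean of the normalized expression over the
#' signature genes, ranks the tumor samples, and labels the top
#' `floor(n/4)` as `"high"`, the bottom `floor(n/4)` as `"low"`, and the
#' rest `"middle"`. Ties are broken by sample ID for determinism; a constant
#' signature average is flagged degenerate. The result is a survival-ready
#' table (sample, signature average, group).
#'
#' @param normalized Genes x samples matrix from [normalize_bulk()].
#' @param signature Character vector of signature gene IDs.
#' @param labels Per-sample tumor/normal labels (named by sample or in
#'   column order); only tumor samples are grouped.
#' @return Data frame (sample, signature_avg, group) with attribute
#'   `"degenerate"` (logical).
#' @export
assign_groups <- function(normalized, signature, labels) {
  if (!is.null(names(labels))) labels <- labels[colnames(normalized)]
  genes <- intersect(signature, rownames(normalized))
  if (length(genes) == 0) stop("no signature genes present in the matrix")
  tumor <- colnames(normalized)[labels == "tumor"]
  n <- length(tumor)
  if (n < 8) stop("need at least 8 tumor samples for quartile grouping")
  avg <- colMeans(normalized[genes, tumor, drop = FALSE])
  k <- floor(n / 4)
  ord <- tumor[order(-avg, tumor)]
  group <- stats::setNames(rep("middle", n), ord)
  group[ord[seq_len(k)]] <- "high"
  group[ord[n - seq_len(k) + 1L]] <- "low"
  out <- data.frame(sample = tumor, signature_avg = as.numeric(avg[tumor]),
                    group = as.character(group[tumor]), row.names = NULL)
  attr(out, "degenerate") <- length(unique(avg)) == 1
  if (attr(out, "degenerate"))
    warning("constant signature average; groups determined by tie-break only")
  out
}
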