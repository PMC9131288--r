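#' Configuration for the synthetic scRNA-seq generator
#'
#' Builds and validates the parameter set for [simulate_counts()]. The
#' generator emulates a multi-sample, two-condition (tumor/normal) droplet
#' scRNA-seq experiment: negative-binomial UMI counts whose log-mean is the
#' sum of a gene baseline, a planted cluster-marker effect, a per-(sample,
#' gene) batch effect, and a per-cell log library-size factor. Cluster
#' membership is drawn per cell from the proportion vector of the sample's
#' condition, so condition-dependent cluster abundances can be planted.
#'
#' @param n_genes Total number of genes, including mitochondrial genes.
#' @param n_cells_per_sample Cells simulated per sample.
#' @param n_samples Number of samples (patients x tissue).
#' @param condition_assignment Character vector of length `n_samples` with
#'   values `"tumor"` or `"normal"`. Default: first half tumor, rest normal.
#' @param cluster_proportions Named list with elements `tumor` and `normal`,
#'   each a probability vector of length `n_clusters` summing to 1.
#'   Default: uniform in both conditions.
#' @param n_clusters Number of true cell clusters.
#' @param marker_plan Data frame with columns `gene`, `cluster`, `log2fc` and
#'   optionally `exclusive` (logical). Marker genes get `log2fc` added (in
#'   log2 units) to their log-mean inside their cluster; `exclusive` markers
#'   additionally have mean zero outside their cluster. Default: 10 markers
#'   per cluster at +3 log2, non-exclusive.
#' @param cluster_cell_types Character vector of length `n_clusters` mapping
#'   each cluster to a major cell type. Default alternates two types so that
#'   cell-type-level statistics are exercised.
#' @param batch_sd Standard deviation of the per-(sample, gene) Gaussian
#'   batch effect on the natural-log mean, applied to every gene.
#' @param n_batch_genes Number of additional "pure batch" genes (drawn from
#'   the non-marker, non-mitochondrial genes) that receive a strong
#'   per-sample effect with standard deviation `batch_gene_sd`. These are the
#'   genes the two-way-ANOVA sample-variance filter is designed to remove.
#' @param batch_gene_sd Standard deviation of the per-sample log-effect for
#'   the strong batch genes.
#' @param dispersion Negative-binomial size (inverse-dispersion) parameter;
#'   larger means closer to Poisson. Must be > 0.
#' @param library_size_lognormal Numeric `c(meanlog, sdlog)` of the per-cell
#'   expected total UMI count.
#' @param mito_fraction_target Expected fraction of a cell's counts carried
#'   by the mitochondrial genes.
#' @param n_mito_genes Number of mitochondrial genes (named with the `MT-`
#'   prefix so QC can identify them).
#' @param seed Integer seed; all draws derive from one stream.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(n_genes = 1000L,
                              n_cells_per_sample = 300L,
                              n_samples = 6L,
                              condition_assignment = NULL,
                              cluster_proportions = NULL,
                              n_clusters = 4L,
                              marker_plan = NULL,
                              cluster_cell_types = NULL,
                              batch_sd = 0.1,
                              n_batch_genes = 0L,
                              batch_gene_sd = 2.5,
                              dispersion = 2,
                              library_size_lognormal = c(log(2000), 0.3),
                              mito_fraction_target = 0.05,
                              n_mito_genes = 20L,
                              seed = 1L) {
  if (n_genes < 1 || n_cells_per_sample < 1 || n_samples < 1 || n_clusters < 1)
    stop("all counts in the configuration must be positive")
  if (dispersion <= 0) stop("dispersion must be > 0")
  if (n_mito_genes >= n_genes) stop("n_mito_genes must be < n_genes")
  if (is.null(condition_assignment)) {
    condition_assignment <- rep(c("tumor", "normal"),
                                c(ceiling(n_samples / 2), floor(n_samples / 2)))
  }
  if (length(condition_assignment) != n_samples ||
      !all(condition_assignment %in% c("tumor", "normal")))
    stop("condition_assignment must be length n_samples with values tumor/normal")
  if (is.null(cluster_proportions)) {
    u <- rep(1 / n_clusters, n_clusters)
    cluster_proportions <- list(tumor = u, normal = u)
  }
  for (cond in c("tumor", "normal")) {
    p <- cluster_proportions[[cond]]
    if (length(p) != n_clusters)
      stop("cluster_proportions$", cond, " must have length n_clusters")
    if (abs(sum(p) - 1) > 1e-9)
      stop("cluster_proportions$", cond, " must sum to 1")
    if (any(p < 0)) stop("cluster proportions must be non-negative")
  }
  genes <- c(sprintf("G%04d", seq_len(n_genes - n_mito_genes)),
             if (n_mito_genes > 0) sprintf("MT-%d", seq_len(n_mito_genes)))
  if (is.null(marker_plan)) {
    n_mk <- 10L
    marker_plan <- data.frame(
      gene = genes[seq_len(n_mk * n_clusters)],
      cluster = rep(seq_len(n_clusters), each = n_mk),
      log2fc = 3,
      exclusive = FALSE
    )
  }
  if (!all(c("gene", "cluster", "log2fc") %in% names(marker_plan)))
    stop("marker_plan needs columns gene, cluster, log2fc")
  if (is.null(marker_plan$exclusive)) marker_plan$exclusive <- FALSE
  if (!all(marker_plan$gene %in% genes))
    stop("marker_plan references genes outside the gene list")
  if (!all(marker_plan$cluster %in% seq_len(n_clusters)))
    stop("marker_plan references unknown clusters")
  if (is.null(cluster_cell_types)) {
    cluster_cell_types <- rep(c("typeA", "typeB"), length.out = n_clusters)
  }
  if (length(cluster_cell_types) != n_clusters)
    stop("cluster_cell_types must have length n_clusters")
  structure(list(
    n_genes = as.integer(n_genes),
    n_cells_per_sample = as.integer(n_cells_per_sample),
    n_samples = as.integer(n_samples),
    condition_assignment = condition_assignment,
    cluster_proportions = cluster_proportions,
    n_clusters = as.integer(n_clusters),
    marker_plan = marker_plan,
    cluster_cell_types = cluster_cell_types,
    batch_sd = batch_sd,
    n_batch_genes = as.integer(n_batch_genes),
    batch_gene_sd = batch_gene_sd,
    dispersion = dispersion,
    library_size_lognormal = library_size_lognormal,
    mito_fraction_target = mito_fraction_target,
    n_mito_genes = as.integer(n_mito_genes),
    genes = genes,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate a multi-sample tumor/normal UMI count matrix with ground truth
#'
#' Draws per-cell cluster membership from the condition-specific proportion
#' vector, then gene-wise negative-binomial counts with log-mean
#' `log(baseline) + log(2) * log2fc[marker] + batch(sample, gene) +
#' log(library factor)`. Mitochondrial gene baselines are scaled so their
#' expected share of each cell's counts equals `mito_fraction_target`.
#' Fully reproducible given `config$seed`.
#'
#' @param config A `sim_config` from [simulation_config()].
#' @return A list with elements
#'   `counts` (sparse `dgCMatrix`, genes x cells),
#'   `cells` (data.frame: barcode, sample, condition, cell_type, true_cluster),
#'   `truth` (list: true_cluster, true_markers, true_batch_genes,
#'   true_enriched_clusters, base_mean, cluster_log2fc, batch_effects).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ng <- config$n_genes
  genes <- config$genes
  mito <- grepl("^MT-", genes)

  # gene baselines: heavily skewed lognormal relative abundances (a few
  # genes carry most of the library, as in real transcriptomes); planted
  # marker and batch genes are pinned at the median baseline so they sit in
  # the detectable mid-abundance range
  base <- stats::rlnorm(ng, meanlog = 0, sdlog = 2)
  base[config$genes %in% config$marker_plan$gene] <-
    stats::quantile(base[!mito], 0.35, names = FALSE)
  if (any(mito) && config$mito_fraction_target > 0) {
    base[mito] <- base[mito] / sum(base[mito]) *
      sum(base[!mito]) * config$mito_fraction_target /
      (1 - config$mito_fraction_target)
  }
  base <- base / sum(base)

  # cluster log2 effects (genes x clusters); exclusive markers silence the
  # gene outside its cluster
  fc <- matrix(0, ng, config$n_clusters, dimnames = list(genes, NULL))
  excl <- matrix(FALSE, ng, config$n_clusters, dimnames = list(genes, NULL))
  mp <- config$marker_plan
  for (i in seq_len(nrow(mp))) {
    fc[mp$gene[i], mp$cluster[i]] <- mp$log2fc[i]
    if (isTRUE(mp$exclusive[i])) {
      excl[mp$gene[i], ] <- TRUE
      excl[mp$gene[i], mp$cluster[i]] <- FALSE
    }
  }

  # batch effects on the natural-log scale, one draw per (gene, sample)
  samples <- sprintf("S%02d", seq_len(config$n_samples))
  batch <- matrix(stats::rnorm(ng * config$n_samples, 0, config$batch_sd),
                  ng, config$n_samples, dimnames = list(genes, samples))
  batch_genes <- character(0)
  if (config$n_batch_genes > 0) {
    pool <- setdiff(genes[!mito], mp$gene)
    if (length(pool) < config$n_batch_genes)
      stop("not enough free genes for n_batch_genes")
    batch_genes <- sample(pool, config$n_batch_genes)
    base[genes %in% batch_genes] <- stats::median(base[!mito])
    base <- base / sum(base)
    # centered per-sample offsets with realized spread exactly batch_gene_sd
    # (randomly ordered per gene), so every planted batch gene really is
    # sample-variable
    spread <- as.numeric(scale(seq_len(config$n_samples)))
    for (g in batch_genes) {
      batch[g, ] <- batch[g, ] + config$batch_gene_sd * sample(spread)
    }
  }

  n_cells <- config$n_cells_per_sample * config$n_samples
  sample_of <- rep(samples, each = config$n_cells_per_sample)
  cond_of <- config$condition_assignment[match(sample_of, samples)]
  clus <- integer(n_cells)
  for (s in seq_along(samples)) {
    idx <- which(sample_of == samples[s])
    p <- config$cluster_proportions[[config$condition_assignment[s]]]
    clus[idx] <- sample.int(config$n_clusters, length(idx),
                            replace = TRUE, prob = p)
  }
  lib <- stats::rlnorm(n_cells, config$library_size_lognormal[1],
                       config$library_size_lognormal[2])

  counts <- matrix(0L, ng, n_cells)
  for (i in seq_len(n_cells)) {
    mu <- base * 2^fc[, clus[i]] * exp(batch[, sample_of[i]])
    mu[excl[, clus[i]]] <- 0
    mu <- mu / sum(mu) * lib[i]
    counts[, i] <- stats::rnbinom(ng, size = config$dispersion, mu = mu)
  }
  barcodes <- sprintf("%s_C%04d", sample_of,
                      stats::ave(seq_len(n_cells), sample_of, FUN = seq_along))
  dimnames(counts) <- list(genes, barcodes)
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")

  cells <- data.frame(
    barcode = barcodes,
    sample = sample_of,
    condition = cond_of,
    cell_type = config$cluster_cell_types[clus],
    true_cluster = clus,
    stringsAsFactors = FALSE
  )
  pt <- config$cluster_proportions$tumor
  pn <- config$cluster_proportions$normal
  truth <- list(
    true_cluster = stats::setNames(clus, barcodes),
    true_markers = stats::setNames(mp$cluster, mp$gene),
    true_batch_genes = batch_genes,
    true_enriched_clusters = which(pt > pn),
    base_mean = stats::setNames(base, genes),
    cluster_log2fc = fc,
    batch_effects = batch
  )
  list(counts = counts, cells = cells, truth = truth)
}

#' Simulate a ligand-receptor pair table with planted active interactions
#'
#' Builds a pair catalogue over the supplied gene universe and, for each
#' planted active triple (sender cluster, receiver cluster, pair), an
#' expression-adjustment plan that elevates the ligand subunits in the sender
#' cluster and the receptor subunits in the receiver cluster strongly enough
#' that well over 25% of those cells detect them. Apply the plan to a count
#' matrix with [apply_expression_plan()].
#'
#' @param n_pairs Number of ligand-receptor pairs.
#' @param n_complex How many of the pairs have a two-subunit receptor complex.
#' @param active List of triples `list(cluster_a, cluster_b, pair_id)` (or a
#'   3-column data.frame) planted as truly interacting.
#' @param gene_ids Gene universe to draw ligand/receptor genes from; must
#'   contain at least `2 * n_pairs + n_complex` genes.
#' @param boost_mean Mean of the Poisson counts added per planted gene in the
#'   target cluster (default 3, giving ~95% detection).
#' @param seed Integer seed.
#' @return List with `pairs` (data.frame: pair_id, ligand_genes,
#'   receptor_genes; subunits semicolon-joined) and `plan` (data.frame: gene,
#'   cluster, add_mean), plus `active` echoed back.
#' @export
simulate_lr_table <- function(n_pairs, n_complex = 0L, active = list(),
                              gene_ids, boost_mean = 3, seed = 1L) {
  set.seed(seed)
  if (n_pairs == 0) {
    return(list(pairs = data.frame(pair_id = character(0),
                                   ligand_genes = character(0),
                                   receptor_genes = character(0)),
                plan = data.frame(gene = character(0), cluster = integer(0),
                                  add_mean = numeric(0)),
                active = active))
  }
  if (n_complex > n_pairs) stop("n_complex cannot exceed n_pairs")
  need <- 2L * n_pairs + n_complex
  if (length(gene_ids) < need)
    stop("gene universe too small for the requested pair table")
  picked <- sample(gene_ids, need)
  lig <- picked[seq_len(n_pairs)]
  rec1 <- picked[n_pairs + seq_len(n_pairs)]
  rec2 <- if (n_complex > 0) picked[2L * n_pairs + seq_len(n_complex)] else character(0)
  receptor <- rec1
  if (n_complex > 0) {
    receptor[seq_len(n_complex)] <-
      paste(rec1[seq_len(n_complex)], rec2, sep = ";")
  }
  pairs <- data.frame(pair_id = sprintf("LR%03d", seq_len(n_pairs)),
                      ligand_genes = lig,
                      receptor_genes = receptor,
                      stringsAsFactors = FALSE)
  if (anyDuplicated(pairs$pair_id)) stop("duplicate pair IDs")

  if (is.data.frame(active)) {
    active <- lapply(seq_len(nrow(active)),
                     function(i) list(active[[1]][i], active[[2]][i], active[[3]][i]))
  }
  plan <- data.frame(gene = character(0), cluster = integer(0),
                     add_mean = numeric(0), stringsAsFactors = FALSE)
  for (a in active) {
    pid <- a[[3]]
    row <- pairs[pairs$pair_id == pid, ]
    if (nrow(row) != 1) stop("active triple references unknown pair ", pid)
    lg <- strsplit(row$ligand_genes, ";", fixed = TRUE)[[1]]
    rg <- strsplit(row$receptor_genes, ";", fixed = TRUE)[[1]]
    plan <- rbind(plan,
                  data.frame(gene = lg, cluster = a[[1]], add_mean = boost_mean),
                  data.frame(gene = rg, cluster = a[[2]], add_mean = boost_mean))
  }
  list(pairs = pairs, plan = plan, active = active)
}

#' Apply an expression-adjustment plan to a count matrix
#'
#' Adds independent Poisson counts (mean `add_mean`) to the listed genes in
#' all cells of the listed clusters. Used to plant active ligand-receptor
#' interactions on top of [simulate_counts()] output.
#'
#' @param counts Sparse genes x cells count matrix.
#' @param cluster_labels Per-cell cluster labels (same order as columns).
#' @param plan Data frame with columns gene, cluster, add_mean.
#' @param seed Integer seed.
#' @return Adjusted sparse count matrix.
#' @export
apply_expression_plan <- function(counts, cluster_labels, plan, seed = 1L) {
  set.seed(seed)
  if (nrow(plan) == 0) return(counts)
  m <- as.matrix(counts[unique(plan$gene), , drop = FALSE])
  for (i in seq_len(nrow(plan))) {
    idx <- which(cluster_labels == plan$cluster[i])
    m[plan$gene[i], idx] <- m[plan$gene[i], idx] +
      stats::rpois(length(idx), plan$add_mean[i])
  }
  out <- counts
  out[rownames(m), ] <- m
  methods::as(methods::as(out, "generalMatrix"), "CsparseMatrix")
}

#' Simulate a bulk TPM cohort with a planted high-signature tumor subset
#'
#' Gene-wise log-normal TPM values for `n_normal` normal and `n_tumor` tumor
#' samples; the signature genes are shifted up by `effect` log2 units in a
#' designated random subset of tumor samples, so quartile grouping can be
#' validated against the planted labels.
#'
#' @param n_tumor Number of tumor samples (>= 4 so quartiles are non-trivial).
#' @param n_normal Number of normal samples (>= 1).
#' @param signature Character vector of signature gene IDs; created if absent
#'   from the background gene list.
#' @param effect Log2 shift applied to signature genes in the high subset.
#' @param frac_high Fraction of tumor samples planted as high (default 0.25).
#' @param n_background Number of unshifted background genes.
#' @param seed Integer seed.
#' @return List with `tpm` (genes x samples matrix), `labels` (named
#'   character vector tumor/normal), `high_samples` (planted high subset).
#' @export
simulate_bulk <- function(n_tumor, n_normal, signature, effect = 2,
                          frac_high = 0.25, n_background = 200L, seed = 1L) {
  if (n_tumor < 4) stop("n_tumor must be >= 4 for non-degenerate quartiles")
  if (n_normal < 1) stop("need at least one normal sample")
  set.seed(seed)
  genes <- unique(c(signature, sprintf("BG%04d", seq_len(n_background))))
  ns <- n_tumor + n_normal
  samp <- c(sprintf("T%02d", seq_len(n_tumor)), sprintf("N%02d", seq_len(n_normal)))
  labels <- stats::setNames(rep(c("tumor", "normal"), c(n_tumor, n_normal)), samp)
  base <- stats::rlnorm(length(genes), meanlog = log(50), sdlog = 1)
  tpm <- matrix(stats::rlnorm(length(genes) * ns, 0, 0.3), length(genes), ns,
                dimnames = list(genes, samp)) * base
  high <- sort(sample(samp[seq_len(n_tumor)], max(1L, round(frac_high * n_tumor))))
  if (effect != 0) {
    tpm[signature, high] <- tpm[signature, high] * 2^effect
  }
  list(tpm = tpm, labels = labels, high_samples = high)
}
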