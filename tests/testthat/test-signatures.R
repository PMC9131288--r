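test_that("cluster specificity boundary identities hold exactly", {
  # 3 clusters x 10 cells; gene expressed only in the focal cluster -> 1
  labels <- rep(1:3, each = 10)
  m <- matrix(0, 2, 30)
  m[1, labels == 1] <- runif(10, 1, 5)
  # gene 2: another cluster high-expressed at least as often -> 0
  m[2, labels == 1] <- c(1:10)
  m[2, labels == 2] <- c(1:10) + 3
  norm <- as_norm(m)
  expect_identical(cluster_specificity(norm, labels, "g01", 1), 1)
  expect_identical(cluster_specificity(norm, labels, "g02", 1), 0)
  # no nonzero value in the focal cluster -> 0
  expect_identical(cluster_specificity(norm, labels, "g01", 3), 0)
  expect_error(cluster_specificity(norm, labels, "g01", 9), "unknown")
})

test_that("specificity scores match the brute-force oracle on constructed and random data", {
  # designed case: focal high fraction 0.7, competitor 0.35 -> score 0.5
  labels <- rep(c("A", "B", "C"), c(10, 20, 20))
  m <- matrix(0, 1, 50)
  m[1, 1:10] <- 1:10                        # t = 3.25, 7/10 above
  m[1, 11:17] <- 4                          # 7/20 above
  norm <- as_norm(m)
  expect_equal(cluster_specificity(norm, labels, "g01", "A"), 0.5)
  expect_equal(oracle_cluster_specificity(norm, labels, "g01", "A"), 0.5)
  # random matrices agree with the independently coded oracle
  set.seed(5)
  for (rep in 1:20) {
    mm <- as_norm(matrix(rpois(3 * 60, 1) * runif(180), 3, 60))
    lab <- sample(1:3, 60, replace = TRUE)
    ty <- sample(c("T", "M"), 60, replace = TRUE)
    g <- sample(rownames(mm), 1)
    f <- sample(unique(lab), 1)
    expect_equal(cluster_specificity(mm, lab, g, f),
                 oracle_cluster_specificity(mm, lab, g, f), tolerance = 1e-12)
    ft <- sample(unique(ty), 1)
    expect_equal(cell_type_specificity(mm, ty, g, ft),
                 oracle_cell_type_specificity(mm, ty, g, ft),
                 tolerance = 1e-12)
  }
})

test_that("cell type specificity boundaries and single-type fallback", {
  types <- rep(c("T", "M"), each = 20)
  m <- matrix(0, 2, 40)
  m[1, types == "T"] <- runif(20, 1, 3)        # exclusive to T -> 1
  m[2, ] <- rep(1:4, 10)                       # uniform across types -> 0
  norm <- as_norm(m)
  expect_identical(cell_type_specificity(norm, types, "g01", "T"), 1)
  expect_equal(cell_type_specificity(norm, types, "g02", "T"), 0,
               tolerance = 1e-12)
  expect_warning(
    one <- cell_type_specificity(norm, rep("T", 40), "g01", "T"),
    "one cell type")
  expect_identical(one, 1)
})

test_that("specificity scores are invariant to monotone rescaling", {
  set.seed(6)
  m <- matrix(rpois(2 * 60, 1) * runif(120, 0.5, 2), 2, 60)
  lab <- rep(1:3, each = 20)
  ty <- rep(c("T", "M"), each = 30)
  norm <- as_norm(m)
  mono <- as_norm(sqrt(m) + m^2)   # strictly increasing on [0, inf)
  for (g in c("g01", "g02")) {
    expect_equal(cluster_specificity(norm, lab, g, 2),
                 cluster_specificity(mono, lab, g, 2), tolerance = 1e-12)
    expect_equal(cell_type_specificity(norm, ty, g, "M"),
                 cell_type_specificity(mono, ty, g, "M"), tolerance = 1e-12)
  }
})

test_that("combined score is the geometric mean with inclusive 0.7 cutoff", {
  labels <- rep(1:2, each = 15)
  types <- rep(c("T", "M"), each = 15)
  m <- matrix(0, 3, 30)
  m[1, 1:15] <- runif(15, 1, 2)    # exclusive to cluster 1 / type T
  m[2, ] <- runif(30, 1, 2)        # everywhere
  m[3, 16:30] <- runif(15, 1, 2)   # exclusive to cluster 2 / type M
  norm <- as_norm(m)
  cand <- data.frame(gene = c("g01", "g02", "g03"), cluster = c(1, 1, 2))
  sig <- identify_signature_genes(norm, labels, types, cand)
  expect_equal(sig$combined^2,
               sig$cluster_specificity * sig$cell_type_specificity,
               tolerance = 1e-12)
  expect_equal(sig$combined[sig$gene == "g01"], 1)
  expect_true(sig$is_signature[sig$gene == "g01"])
  expect_equal(sig$combined[sig$gene == "g02"], 0)  # annihilation
  expect_false(sig$is_signature[sig$gene == "g02"])
  expect_equal(sig$gene[1], "g01")   # sorted by combined, then gene
})

test_that("planted Treg-style exclusive markers are all flagged as signatures", {
  treg_markers <- c("IL2RA", "BATF", "FOXP3", "TIGIT", "CTLA4", "ICOS")
  set.seed(12)
  labels <- rep(1:3, each = 30)          # cluster 1 = the Treg-like cluster
  types <- rep(c("T", "T", "M"), each = 30)
  m <- matrix(rpois(10 * 90, 0.2), 10, 90)
  m <- rbind(m, matrix(0, 6, 90))
  rownames(m) <- c(sprintf("bg%02d", 1:10), treg_markers)
  for (g in treg_markers) m[g, labels == 1] <- runif(30, 1, 4)
  norm <- as_norm(m, genes = rownames(m))
  sig <- identify_signature_genes(norm, labels, types,
                                  data.frame(gene = treg_markers, cluster = 1))
  expect_true(all(sig$is_signature))
  expect_true(all(sig$combined == 1))
})

test_that("gene set scoring averages present genes and reports missing ones", {
  m <- matrix(c(1, 2, 3, 4, 5,
                0, 0, 0, 0, 10), 5, 2)
  norm <- as_norm(m, genes = c("PDCD1", "LAG3", "TIGIT", "HAVCR2", "CTLA4"))
  sc <- gene_set_score(norm, c("PDCD1", "LAG3", "TIGIT", "HAVCR2", "CTLA4"))
  expect_equal(as.numeric(sc), c(3, 2))
  single <- gene_set_score(norm, "CTLA4")
  expect_equal(as.numeric(single), as.numeric(m[5, ]))
  part <- gene_set_score(norm, c("PDCD1", "LAG3", "TIGIT", "XXX"))
  expect_equal(attr(part, "missing_genes"), "XXX")
  expect_equal(as.numeric(part), colMeans(m[1:3, ]))
  expect_error(gene_set_score(norm, c("A", "B", "C", "PDCD1")), "coverage")
})

test_that("rank-sum p-values agree with stats::wilcox.test", {
  set.seed(13)
  m <- matrix(rpois(10 * 40, 2) * runif(400), 10, 40)
  norm <- as_norm(m)
  res <- de_test(norm, 1:20, 21:40)
  for (g in 1:10) {
    ref <- suppressWarnings(
      stats::wilcox.test(m[g, 1:20], m[g, 21:40], exact = FALSE))$p.value
    expect_equal(res$p[g], ref, tolerance = 1e-9)
  }
})

test_that("DE null produces nominal raw positives and no BH discoveries", {
  set.seed(14)
  n_genes <- 1000
  m <- matrix(rpois(n_genes * 120, 1.5), n_genes, 120)
  norm <- normalize_counts(as_norm(m + 1))   # +1 avoids zero-total columns
  res <- de_test(norm, 1:60, 61:120)         # identical populations
  expect_lt(mean(res$p < 0.05), 0.08)
  expect_gt(mean(res$p < 0.05), 0.02)
  expect_equal(sum(res$passes_filter), 0)
  expect_lt(sum(res$p_adj < 0.05), 3)
})

test_that("the DE filter applies the percent, fold-change and FDR thresholds", {
  set.seed(15)
  n <- 200
  shifted <- c(rpois(n, 4), rpois(n, 0.5))          # planted ~4-fold shift
  rare <- rbinom(2 * n, 1, 0.05) * 5                # 5% expression, both
  flat <- rpois(2 * n, 2)
  m <- rbind(shifted, rare, flat, rpois(2 * n, 3) + 1)
  norm <- normalize_counts(as_norm(m))
  res <- de_test(norm, 1:n, (n + 1):(2 * n))
  expect_true(res$passes_filter[1])
  expect_false(res$passes_filter[2])                # fails percent filter
  expect_lte(max(res$pct_a[2], res$pct_b[2]), 0.10)
  expect_false(res$passes_filter[3])
  expect_error(de_test(norm, 1:2, 3:10), "at least 3")
})
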