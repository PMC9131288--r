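test_that("the detection filter applies the strict >25% all-subunit rule", {
  # 100 cells, 2 clusters of 50; engineered detection fractions
  lab <- rep(1:2, each = 50)
  m <- matrix(0, 4, 100)
  m[1, 1:13] <- 1            # ligand L1: 26% in cluster 1
  m[2, 51:90] <- 1           # receptor R1: 80% in cluster 2
  m[3, 1:12] <- 1            # ligand L2: exactly 25% -> excluded
  m[4, 51:55] <- 1           # receptor subunit R2b: 10% -> kills complex
  norm <- as_norm(m, genes = c("L1", "R1", "L2", "R2b"))
  lr <- data.frame(pair_id = c("P1", "P2", "P3"),
                   ligand_genes = c("L1", "L2", "L1"),
                   receptor_genes = c("R1", "R1", "R1;R2b"))
  flt <- expression_filter(norm, lab, lr)
  get <- function(p, a, b) flt$tested[flt$pair_id == p & flt$cluster_a == a &
                                        flt$cluster_b == b]
  expect_true(get("P1", 1, 2))
  expect_false(get("P2", 1, 2))        # 25.0% exactly is not "more than 25%"
  expect_false(get("P3", 1, 2))        # one complex subunit below threshold
  expect_false(get("P1", 2, 1))        # direction matters
  # brute-force counting oracle over every combination
  det <- sapply(1:2, function(cl)
    rowMeans(as.matrix(norm)[, lab == cl, drop = FALSE] > 0))
  for (i in seq_len(nrow(flt))) {
    lg <- strsplit(lr$ligand_genes[match(flt$pair_id[i], lr$pair_id)], ";")[[1]]
    rg <- strsplit(lr$receptor_genes[match(flt$pair_id[i], lr$pair_id)], ";")[[1]]
    expect_equal(flt$tested[i],
                 all(det[lg, flt$cluster_a[i]] > 0.25) &&
                   all(det[rg, flt$cluster_b[i]] > 0.25))
  }
})

test_that("the interaction statistic averages means with the min-subunit rule", {
  lab <- rep(1:2, each = 10)
  m <- rbind(L = c(rep(2, 10), rep(0, 10)),
             R1 = c(rep(0, 10), rep(4, 10)),
             R2 = c(rep(0, 10), rep(1, 10)))
  norm <- as_norm(m, genes = rownames(m))
  expect_equal(interaction_statistic(norm, lab, "L", "R1", 1, 2), 3)
  # complex: the subunit with minimum mean (1) is used -> (2 + 1) / 2
  expect_equal(interaction_statistic(norm, lab, "L", c("R1", "R2"), 1, 2), 1.5)
  # brute-force recomputation on a random matrix
  set.seed(50)
  mm <- as_norm(matrix(runif(5 * 40), 5, 40))
  lab2 <- sample(1:2, 40, replace = TRUE)
  st <- interaction_statistic(mm, lab2, "g01", c("g02", "g03"), 1, 2)
  manual <- (mean(mm["g01", lab2 == 1]) +
               min(mean(mm["g02", lab2 == 2]), mean(mm["g03", lab2 == 2]))) / 2
  expect_equal(st, manual, tolerance = 1e-12)
})

test_that("permutation p-values use the add-one rule and a shared stream", {
  set.seed(51)
  lab <- rep(1:3, each = 40)
  m <- matrix(runif(6 * 120), 6, 120)
  norm <- as_norm(m)
  lr <- data.frame(pair_id = c("P1", "P2"),
                   ligand_genes = c("g01", "g03"),
                   receptor_genes = c("g02", "g04"))
  res <- suppressWarnings(permutation_test(norm, lab, lr, n_perm = 99, seed = 7))
  p <- res$results$empirical_p[res$results$tested]
  expect_true(all(p >= 1 / 100 & p <= 1))
  res2 <- suppressWarnings(permutation_test(norm, lab, lr, n_perm = 99, seed = 7))
  expect_identical(res$results, res2$results)
  # constant gene: observed equals every permuted statistic -> p = 1
  mc <- as_norm(matrix(1, 2, 120), genes = c("cl", "cr"))
  lrc <- data.frame(pair_id = "PC", ligand_genes = "cl",
                    receptor_genes = "cr")
  resc <- suppressWarnings(permutation_test(mc, lab, lrc, n_perm = 99, seed = 7))
  expect_true(all(resc$results$empirical_p[resc$results$tested] == 1))
  expect_warning(permutation_test(norm, lab, lr, n_perm = 50, seed = 1),
                 "n_perm")
})

test_that("an empty pair table yields an empty result", {
  lab <- rep(1:2, each = 30)
  norm <- as_norm(matrix(runif(60), 1, 60))
  lr <- simulate_lr_table(0, gene_ids = "g01")$pairs
  res <- permutation_test(norm, lab, lr, n_perm = 100, seed = 1)
  expect_equal(nrow(res$results), 0)
  expect_true(all(res$counts == 0))
})

test_that("a planted interaction is detected and a silent subunit kills the pair", {
  cfg <- simulation_config(n_genes = 400, n_cells_per_sample = 80,
                           n_samples = 4, n_clusters = 3, seed = 52)
  sim <- simulate_counts(cfg)
  lr <- simulate_lr_table(5, n_complex = 0,
                          active = list(list(1, 2, "LR002")),
                          gene_ids = sprintf("G%04d", 150:350), seed = 53)
  counts <- apply_expression_plan(sim$counts, sim$cells$true_cluster,
                                  lr$plan, seed = 54)
  norm <- normalize_counts(counts)
  res <- permutation_test(norm, sim$cells$true_cluster, lr$pairs,
                          n_perm = 200, seed = 55)
  hit <- res$results[res$results$pair_id == "LR002" &
                       res$results$cluster_a == 1 &
                       res$results$cluster_b == 2, ]
  expect_true(hit$tested)
  expect_lte(hit$empirical_p, 0.05)
  # a complex whose second subunit is silent never passes the filter
  lr2 <- data.frame(pair_id = "PX",
                    ligand_genes = lr$pairs$ligand_genes[2],
                    receptor_genes = paste0(lr$pairs$receptor_genes[2],
                                            ";ABSENT"))
  flt <- expression_filter(norm, sim$cells$true_cluster, lr2)
  expect_false(any(flt$tested))
})

test_that("null interactions give roughly uniform empirical p-values", {
  set.seed(56)
  lab <- sample(1:4, 400, replace = TRUE)
  m <- matrix(rpois(30 * 400, 2), 30, 400)     # no cluster structure
  norm <- normalize_counts(as_norm(m + 1))
  lr <- data.frame(pair_id = sprintf("P%02d", 1:15),
                   ligand_genes = sprintf("g%02d", 1:15),
                   receptor_genes = sprintf("g%02d", 16:30))
  res <- permutation_test(norm, lab, lr, n_perm = 100, seed = 57)
  p <- res$results$empirical_p[res$results$tested]
  expect_gt(length(p), 150)
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
  # expected significant fraction near alpha
  expect_lt(mean(p < 0.05), 0.12)
})
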