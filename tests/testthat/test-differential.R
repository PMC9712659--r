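test_that("rank-sum p matches the enumeration oracle exactly for small groups", {
  expect_equal(rank_sum_test(1:3, 4:6)$p_value, 0.1)
  set.seed(21)
  for (i in 1:25) {
    x <- sample(0:5, sample(3:8, 1), replace = TRUE)
    y <- sample(0:5, sample(3:8, 1), replace = TRUE)
    expect_equal(rank_sum_test(x, y)$p_value, oracle_ranksum_p(x, y),
                 tolerance = 1e-12)
  }
})

test_that("normal approximation tracks the exact p and base wilcox.test", {
  set.seed(22)
  for (i in 1:30) {
    x <- runif(sample(5:8, 1)); y <- runif(sample(5:8, 1))
    pa <- rank_sum_test(x, y, exact = FALSE)$p_value
    expect_lt(abs(pa - oracle_ranksum_p(x, y)), 0.02)
    pw <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
    expect_equal(pa, pw, tolerance = 1e-9)
  }
  # tied data agree with wilcox.test's tie-corrected approximation too
  x <- c(1, 1, 2, 3, 3, 3, 4, 5, 6, 6)
  y <- c(2, 2, 2, 3, 4, 4, 5, 5, 6, 7)
  expect_equal(rank_sum_test(x, y, exact = FALSE)$p_value,
               stats::wilcox.test(x, y, exact = FALSE)$p.value,
               tolerance = 1e-9)
})

test_that("BH adjustment equals the step-up definition and preserves order", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(23)
  for (i in 1:20) {
    p <- runif(sample(5:200, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("wilcoxon_de applies the min.pct and logfc gates before testing", {
  # one clear DE gene, one gene expressed in 10% of cells on both sides,
  # one flat gene
  a <- rbind(de = c(3, 3, 3, 3, 3, 0, 0, 0, 0, 0) + 1,
             sparse = c(2, rep(0, 9)),
             flat = rep(1, 10))
  b <- rbind(de = rep(0.2, 10),
             sparse = c(2, rep(0, 9)),
             flat = rep(1, 10))
  norm <- mk_expr(cbind(a, b))
  grp_a <- colnames(norm)[1:10]; grp_b <- colnames(norm)[11:20]
  res <- wilcoxon_de(norm, grp_a, grp_b, min_pct = 0.25, logfc_threshold = 0.25)
  expect_true("de" %in% res$gene)
  expect_false("sparse" %in% res$gene)   # max pct 0.1 < 0.25
  expect_false("flat" %in% res$gene)     # |log2FC| = 0 < 0.25
  # identical distributions: log2FC 0 and exact p ~ 1
  res0 <- wilcoxon_de(norm, grp_a, grp_b, min_pct = 0, logfc_threshold = 0)
  flat <- res0[res0$gene == "flat", ]
  expect_equal(flat$log2_fold_change, 0)
  expect_gte(flat$p_value, 0.99)
  expect_true(all(res0$p_adjusted >= res0$p_value - 1e-12))
  expect_error(wilcoxon_de(norm, grp_a, grp_a), "disjoint")
})

test_that("log2FC follows the de-logged pseudocount-1 convention", {
  a <- matrix(log1p(c(4, 4, 4, 4)), 1)
  b <- matrix(log1p(c(1, 1, 1, 1)), 1)
  norm <- mk_expr(cbind(a, b), genes = "g")
  res <- wilcoxon_de(norm, colnames(norm)[1:4], colnames(norm)[5:8],
                     min_pct = 0, logfc_threshold = 0)
  expect_equal(res$log2_fold_change, log2(5 / 2))
})

test_that("find_all_markers is a symmetric one-vs-rest decomposition", {
  set.seed(24)
  cfg <- sim_config(cells = data.frame(cluster = c("A", "B"), genotype = "WT",
                                       treatment = "x", n = 50),
                    n_genes = 60,
                    cluster_markers = data.frame(gene = c("MkA", "MkB"),
                                                 cluster = c("A", "B"),
                                                 fold = 8),
                    seed = 25)
  sim <- simulate_dataset(cfg)
  norm <- lognormalize(sim$counts)
  mk <- find_all_markers(norm, sim$meta$cluster, min_pct = 0, logfc_threshold = 0)
  # two clusters: same genes, sign-flipped fold changes
  a <- mk[mk$cluster == "A", ]; b <- mk[mk$cluster == "B", ]
  shared <- intersect(a$gene, b$gene)
  expect_equal(a$log2_fold_change[match(shared, a$gene)],
               -b$log2_fold_change[match(shared, b$gene)], tolerance = 1e-9)
  # planted markers significant in their own cluster with positive fold
  for (g in c("MkA", "MkB")) {
    cl <- ifelse(g == "MkA", "A", "B")
    row <- mk[mk$gene == g & mk$cluster == cl, ]
    expect_lt(row$p_adjusted, 0.05)
    expect_gt(row$log2_fold_change, 0)
  }
  expect_error(find_all_markers(norm, rep("A", ncol(norm))), "2 clusters")
})

test_that("percentile gating returns strictly-above-threshold cells", {
  sc <- mk_expr(matrix(1:10, 1), genes = "Ccr2")
  got <- gate_positive_cells(sc, "Ccr2", percentile = 70)
  expect_equal(oracle_pctl(1:10, 70), 7.3)
  expect_setequal(got, colnames(sc)[8:10])
  expect_setequal(gate_positive_cells(sc, "Ccr2", 0), colnames(sc)[2:10])
  const <- mk_expr(matrix(1, 1, 5), genes = "Ccr2")
  expect_length(gate_positive_cells(const, "Ccr2", 70), 0)
  expect_error(gate_positive_cells(sc, "Nope"), "absent")
})

test_that("hypergeometric enrichment equals binomial-coefficient enumeration", {
  u <- paste0("G", 1:10)
  res <- hypergeom_enrichment(u[1:5], u[c(1, 2, 3, 8)], u)
  expect_equal(res$overlap, 3)
  expect_equal(res$p_value, 66 / 252, tolerance = 1e-12)
  expect_equal(res$p_value, oracle_hyper_p(3, 4, 10, 5), tolerance = 1e-12)
  # certain event and near-null overlap
  expect_equal(hypergeom_enrichment(u, u, u)$p_value, 1)
  expect_gt(hypergeom_enrichment(u[5:9], u[1], u)$p_value, 0.4)
  expect_error(hypergeom_enrichment(c("X"), u[1], u), "universe")
})
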