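test_that("orientation standardization flips and deduplicates", {
  raw <- data.frame(ligand = c("Ccr5", "Ccl5", "Ccl7"),
                    receptor = c("Ccl5", "Ccr5", "Ccr2"),
                    orientation = c("receptor-ligand", "ligand-receptor",
                                    "ligand-receptor"))
  expect_warning(out <- standardize_orientation(raw), "duplicate")
  expect_equal(nrow(out), 2)
  expect_equal(out$ligand[1], "Ccl5")
  expect_equal(out$receptor[1], "Ccr5")
  ok <- data.frame(ligand = "Ccl2", receptor = "Ccr2",
                   orientation = "ligand-receptor")
  expect_identical(standardize_orientation(ok)[, 1:2], ok[, 1:2])
  bad <- data.frame(ligand = "a", receptor = "b", orientation = "sideways")
  expect_error(standardize_orientation(bad), "orientation")
})

test_that("pair means average ligand-in-sender with receptor-in-receiver", {
  # ligand mean 2 in sender S, receptor mean 4 in receiver R -> pair mean 3
  norm <- mk_expr(rbind(Lig = c(2, 2, 0, 0), Rec = c(0, 0, 4, 4)))
  cl <- c("S", "S", "R", "R")
  pairs <- data.frame(ligand = "Lig", receptor = "Rec")
  pm <- lr_pair_means(norm, cl, pairs)
  row <- pm[pm$sender == "S" & pm$receiver == "R", ]
  expect_equal(row$pair_mean, 3)
  expect_true(row$expressed_flag)
  # zero-everywhere pair: mean 0 and not expressed
  norm0 <- mk_expr(rbind(Lig = rep(0, 4), Rec = rep(0, 4)))
  pm0 <- lr_pair_means(norm0, cl, pairs)
  expect_true(all(pm0$pair_mean == 0))
  expect_false(any(pm0$expressed_flag))
  # role-exchange symmetry
  rev_pairs <- data.frame(ligand = "Rec", receptor = "Lig")
  pm_rev <- lr_pair_means(norm, cl, rev_pairs)
  expect_equal(pm_rev$pair_mean[pm_rev$sender == "R" & pm_rev$receiver == "S"],
               row$pair_mean)
  # absent gene rows are skipped with a warning
  expect_warning(lr_pair_means(norm, cl, rbind(pairs,
    data.frame(ligand = "Nope", receptor = "Rec"))), "skipped")
})

test_that("planted sender-receiver pair dominates the cluster-pair grid", {
  cfg <- sim_config(cells = data.frame(cluster = c("A", "B", "C"),
                                       genotype = "WT", treatment = "x", n = 60),
                    n_genes = 60,
                    lr_spec = data.frame(ligand = "Ccl5", receptor = "Ccr5",
                                         sender = "A", receiver = "B", fold = 8),
                    seed = 51)
  sim <- simulate_dataset(cfg)
  norm <- lognormalize(sim$counts)
  pm <- lr_pair_means(norm, sim$meta$cluster,
                      data.frame(ligand = "Ccl5", receptor = "Ccr5"))
  best <- pm[which.max(pm$pair_mean), ]
  expect_equal(c(best$sender, best$receiver), c("A", "B"))
})

test_that("permutation p-values live on the add-one grid and hit the floor
           for an exclusive pair", {
  set.seed(52)
  n_per <- 30
  lig <- c(rep(5, n_per), rep(0, 2 * n_per)) + rpois(3 * n_per, 0.1) * c(rep(1, n_per), rep(0, 2 * n_per))
  rec <- c(rep(0, n_per), rep(5, n_per), rep(0, n_per))
  norm <- mk_expr(rbind(Lig = lig, Rec = rec))
  cl <- rep(c("S", "R", "O"), each = n_per)
  res <- lr_permutation_test(norm, cl, data.frame(ligand = "Lig", receptor = "Rec"),
                             n_perm = 199, seed = 3)
  expect_true(all(is.na(res$p_value) |
                    (res$p_value >= 1 / 200 & res$p_value <= 1)))
  grid_ok <- res$p_value[!is.na(res$p_value)] * 200
  expect_equal(grid_ok, round(grid_ok), tolerance = 1e-9)
  # the exclusive sender->receiver pair cannot be beaten by any shuffle
  expect_equal(res$p_value[res$sender == "S" & res$receiver == "R"], 1 / 200)
  # determinism under a fixed seed
  res2 <- lr_permutation_test(norm, cl, data.frame(ligand = "Lig",
                                                   receptor = "Rec"),
                              n_perm = 199, seed = 3)
  expect_identical(res$p_value, res2$p_value)
  expect_warning(lr_permutation_test(norm, cl,
                                     data.frame(ligand = "Lig", receptor = "Rec"),
                                     n_perm = 50, seed = 1), "coarse")
})

test_that("differential pair test recovers a planted fold change", {
  set.seed(53)
  # identical groups: log2FC 0, p ~ 1
  x <- mk_expr(rbind(L = rep(c(1, 2), 10), R = rep(c(2, 1), 10)))
  same <- lr_differential(x, x, data.frame(ligand = "L", receptor = "R"))
  expect_equal(same$log2_fold_change, 0)
  expect_gt(same$p_value, 0.9)
  # 4-fold down in group A over 200 cells/group
  cfg_a <- sim_config(cells = data.frame(cluster = "M", genotype = "Mut",
                                         treatment = "x", n = 200),
                      n_genes = 40,
                      genotype_effects = data.frame(gene = c("Ccl2", "Ccr2"),
                                                    genotype = "Mut",
                                                    fold = 0.25),
                      seed = 54)
  cfg_b <- sim_config(cells = data.frame(cluster = "M", genotype = "WT",
                                         treatment = "x", n = 200),
                      n_genes = 40,
                      genotype_effects = data.frame(gene = c("Ccl2", "Ccr2"),
                                                    genotype = "Mut",
                                                    fold = 0.25),
                      seed = 55)
  na <- lognormalize(simulate_dataset(cfg_a)$counts)
  nb <- lognormalize(simulate_dataset(cfg_b)$counts)
  pairs <- data.frame(ligand = c("Ccl2", "Bg0001"),
                      receptor = c("Ccr2", "Bg0002"))
  diff <- lr_differential(na, nb, pairs)
  planted <- diff[diff$ligand == "Ccl2", ]
  expect_lt(planted$p_adjusted, 0.05)
  expect_lt(planted$log2_fold_change, 0)
  expect_error(lr_differential(na[, 1:2], nb, pairs), "3 cells")
})
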