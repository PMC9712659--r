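test_that("AUC recovery-curve edge cases follow hand enumeration", {
  # 100 genes, window k = 5; expression decreasing so gene g001 has rank 1
  x <- mk_expr(matrix(100:1, 100, 1), genes = sprintf("g%03d", 1:100))
  # single target at rank 1: curve is 1,1,1,1,1 -> area 5; max area 5
  expect_equal(regulon_auc(x, "g001", top_fraction = 0.05)[1, 1], 1)
  # single target at rank 3: curve 0,0,1,1,1 -> area 3 of max 5
  expect_equal(regulon_auc(x, "g003", top_fraction = 0.05)[1, 1], 3 / 5)
  # targets exactly the top |set| ranks -> maximal recovery
  expect_equal(regulon_auc(x, c("g001", "g002", "g003"), 0.05)[1, 1], 1)
  # no target inside the window -> 0
  expect_equal(regulon_auc(x, c("g050", "g099"), 0.05)[1, 1], 0)
  expect_error(regulon_auc(x, c("absent")), "no targets")
})

test_that("AUC scores stay in [0,1] and are seed-stable under ties", {
  set.seed(41)
  x <- mk_expr(matrix(rpois(200 * 20, 1), 200, 20))
  regs <- list(r1 = rownames(x)[1:10], r2 = rownames(x)[50:80])
  a1 <- regulon_auc(x, regs, seed = 7)
  a2 <- regulon_auc(x, regs, seed = 7)
  expect_identical(a1, a2)
  expect_true(all(a1 >= 0 & a1 <= 1))
})

test_that("mean AUC of random gene sets matches the hypergeometric expectation", {
  set.seed(42)
  n_genes <- 400
  x <- mk_expr(matrix(rpois(n_genes * 10, 3), n_genes, 10))
  m <- 30
  sets <- lapply(1:300, function(i) sample(rownames(x), m))
  names(sets) <- paste0("s", 1:300)
  scores <- regulon_auc(x, sets, top_fraction = 0.05, seed = 2)
  exp_mean <- scdownstream:::expected_random_auc(n_genes, m, 0.05)
  se <- sd(colMeans(scores)) / sqrt(length(sets))
  expect_lt(abs(mean(scores) - exp_mean), 4 * se + 0.005)
})

test_that("module score: null equals zero, shift-invariant, seed-stable", {
  # set = whole universe with identical expression -> exactly 0
  flat <- mk_expr(matrix(2, 50, 4))
  expect_equal(unname(module_score(flat, rownames(flat))), rep(0, 4))
  set.seed(43)
  x <- as.matrix(mk_expr(matrix(rpois(80 * 12, 4), 80, 12)))
  s1 <- module_score(x, rownames(x)[1:10], seed = 5)
  expect_identical(s1, module_score(x, rownames(x)[1:10], seed = 5))
  # adding a constant to every gene of a cell cancels between set and control
  shifted <- sweep(x, 2, seq_len(ncol(x)), "+")
  s2 <- module_score(shifted, rownames(x)[1:10], seed = 5)
  expect_equal(unname(s1), unname(s2), tolerance = 1e-12)
  expect_error(module_score(x, "missing"), "no genes")
})

test_that("module scores separate a planted-active cluster", {
  regs <- list(TFa = sprintf("T%02d", 1:15))
  cfg <- sim_config(cells = data.frame(cluster = c("A", "B"), genotype = "WT",
                                       treatment = "x", n = 80),
                    n_genes = 150, regulons = regs,
                    regulon_active = data.frame(regulon = "TFa", cluster = "A",
                                                fold = 4),
                    seed = 44)
  sim <- simulate_dataset(cfg)
  norm <- lognormalize(sim$counts)
  sc <- module_score(norm, regs$TFa, seed = 1)
  in_a <- sim$meta$cluster == "A"
  p <- stats::wilcox.test(sc[in_a], sc[!in_a], alternative = "greater",
                          exact = FALSE)$p.value
  expect_lt(p, 0.01)
})

test_that("the differential-regulon ledger enforces all three filter criteria", {
  set.seed(45)
  n_cells <- 60
  cond <- rep(c("Mut", "WT"), each = n_cells / 2)
  # three regulons: diff+expressed (passes), diff but zero expression
  # (criterion 1), diff with too few DEGs (criterion 3)
  scores <- cbind(pass = c(rnorm(30, 1), rnorm(30, 0)),
                  silent = c(rnorm(30, 1), rnorm(30, 0)),
                  fewdeg = c(rnorm(30, 1), rnorm(30, 0)))
  rownames(scores) <- paste0("c", seq_len(n_cells))
  regulons <- list(pass = paste0("P", 1:10),
                   silent = paste0("S", 1:10),
                   fewdeg = paste0("F", 1:40))
  norm <- mk_expr(rbind(matrix(1, 10, n_cells), matrix(0, 10, n_cells),
                        matrix(1, 40, n_cells)),
                  genes = c(regulons$pass, regulons$silent, regulons$fewdeg),
                  cells = rownames(scores))
  de <- data.frame(gene = c(paste0("P", 1:3), "S1", "F1"), p_adjusted = 1e-6)
  led <- differential_regulons(scores, cond, de, regulons, norm = norm,
                               group1 = "Mut")
  led <- led[match(c("pass", "silent", "fewdeg"), led$regulon), ]
  # silent fails only the expression criterion, fewdeg only the 5% rule
  expect_equal(led$pass_flag, c(TRUE, FALSE, FALSE))
  expect_equal(led$n_DEG_targets, c(3, 1, 1))
  expect_equal(led$DEG_fraction, c(0.3, 0.1, 1 / 40))
  # regulon of 40 targets with 1 DEG fails the 5% proportion rule
  expect_lt(led$DEG_fraction[3], 0.05)
  expect_error(differential_regulons(scores, rep(c("a", "b", "c"), 20), de,
                                     regulons, norm = norm),
               "exactly 2")
})

test_that("ledger p-values are near-uniform under a null simulation", {
  set.seed(46)
  n_reg <- 150
  scores <- matrix(rnorm(80 * n_reg), 80, n_reg,
                   dimnames = list(paste0("c", 1:80), paste0("r", 1:n_reg)))
  regulons <- setNames(lapply(1:n_reg, function(i) paste0("G", i)),
                       colnames(scores))
  norm <- mk_expr(matrix(1, n_reg, 80), genes = paste0("G", 1:n_reg),
                  cells = rownames(scores))
  de <- data.frame(gene = character(0), p_adjusted = numeric(0))
  led <- differential_regulons(scores, rep(c("a", "b"), 40), de, regulons,
                               norm = norm)
  ks <- suppressWarnings(stats::ks.test(led$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_false(any(led$pass_flag))  # no DEGs -> criterion 2 blocks all
})
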