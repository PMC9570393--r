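test_that("AUC matches the pair-counting examples", {
  expect_equal(auc(c(3, 5), c(1, 4)), 0.75)
  expect_equal(auc(c(5, 6, 7), c(1, 2)), 1)
  expect_equal(auc(c(1, 1), c(1, 1)), 0.5)
  expect_error(auc(numeric(0), 1), "non-empty")
})

test_that("AUC equals the brute-force pair count and is antisymmetric", {
  for (seed in 1:30) {
    set.seed(seed)
    a <- sample(1:6, sample(2:8, 1), replace = TRUE) # ties likely
    b <- sample(1:6, sample(2:8, 1), replace = TRUE)
    expect_equal(auc(a, b), brute_auc(a, b))
    expect_equal(auc(a, b) + auc(b, a), 1)
  }
})

test_that("trapezoidal area under roc_points equals the Mann-Whitney AUC", {
  for (seed in 1:10) {
    set.seed(seed)
    a <- round(rnorm(15), 1); b <- round(rnorm(12), 1)
    rp <- roc_points(a, b)
    expect_true(all(diff(rp$fpr) >= 0) && all(diff(rp$tpr) >= 0))
    expect_equal(rp$fpr[1], 0); expect_equal(rp$tpr[nrow(rp)], 1)
    trap <- sum(diff(rp$fpr) * (head(rp$tpr, -1) + tail(rp$tpr, -1)) / 2)
    expect_equal(trap, auc(a, b), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(3)
  a <- rnorm(20, 1); b <- rnorm(15)
  ref <- as.numeric(pROC::auc(rep(c(1, 0), c(20, 15)), c(a, b),
                              direction = "<", quiet = TRUE))
  expect_equal(auc(a, b), ref)
})

test_that("group test gates between t and rank-sum and handles degeneracy", {
  # separation: p tiny
  set.seed(6)
  r <- group_test(rnorm(20) + 10, rnorm(20))
  expect_lt(r$p_value, 1e-6)
  # identical groups: p = 1 via the rank-sum branch
  r2 <- group_test(rep(2, 5), rep(2, 5))
  expect_equal(r2$test_used, "wilcoxon")
  expect_equal(r2$p_value, 1)
  # exact two-sided rank-sum on fully separated tiny groups (U = 0):
  # 2 * C(3,3)^{-1}-style enumeration over C(6,3)=20 assignments gives 0.1
  r3 <- group_test(c(1, 2, 3), c(4, 5, 6), force = "wilcoxon")
  expect_equal(r3$p_value, 0.1)
  # heavy-tailed data routes to the rank-sum branch
  set.seed(60)
  r4 <- group_test(rcauchy(30), rcauchy(30))
  expect_equal(r4$test_used, "wilcoxon")
})

test_that("Spearman rho equals Pearson on mid-ranks and handles monotone maps", {
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 5)
  st <- spearman_test(x, y)
  # 1 - 6*sum(d^2)/(n(n^2-1)) with sum(d^2) = 4
  expect_equal(st$rho, 0.8)
  expect_equal(st$rho, cor(rank(x), rank(y)), tolerance = 1e-12)
  xx <- rnorm(20)
  expect_equal(spearman_test(xx, exp(xx))$rho, 1)
  expect_equal(spearman_test(xx, -xx^3)$rho, -1)
})

test_that("exact permutation p matches brute force for small n", {
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 5)
  st <- spearman_test(x, y)
  perms <- e1071::permutations(5)
  rhos <- apply(perms, 1, function(p) cor(rank(x), rank(y[p])))
  expect_equal(st$p_value, mean(abs(rhos) >= abs(st$rho) - 1e-12))
  # and for a tied case
  x2 <- c(1, 1, 2, 3, 4, 5); y2 <- c(3, 1, 4, 1, 5, 2)
  st2 <- spearman_test(x2, y2)
  perms6 <- e1071::permutations(6)
  rhos2 <- apply(perms6, 1, function(p) cor(rank(x2), rank(y2[p])))
  expect_equal(st2$p_value, mean(abs(rhos2) >= abs(st2$rho) - 1e-12))
})

test_that("large-n Spearman p uses the t approximation", {
  set.seed(14)
  x <- rnorm(50); y <- x + rnorm(50)
  st <- spearman_test(x, y)
  tt <- st$rho * sqrt(48 / (1 - st$rho^2))
  expect_equal(st$p_value, 2 * pt(-abs(tt), 48))
})

test_that("evaluate_genes scores both cohorts with AUCs in [0, 1]", {
  sim <- simulate_expression(sim_config(n_case = 40, n_control = 15,
                                        n_genes = 100, n_de = 3,
                                        logfc_values = rep(2, 3),
                                        noise_sd = 0.4, seed = 8))
  sp <- split_samples(sim$es, 0.8, 8)
  tab <- evaluate_genes(sim$es, sp, sim$truth$de_gene_ids)
  expect_equal(nrow(tab), 6)
  expect_true(all(tab$auc >= 0 & tab$auc <= 1))
  expect_true(all(tab$auc > 0.8)) # strong planted effect
  expect_error(evaluate_genes(sim$es, sp, "nope"), "unknown genes")
})

test_that("immune correlation recovers planted link signs", {
  cfg <- sim_config(n_case = 60, n_control = 60, n_genes = 50, n_de = 4,
                    logfc_values = rep(1.5, 4), n_batches = 1,
                    batch_shift_sd = 0, seed = 11)
  sim <- simulate_expression(cfg)
  fr <- simulate_cell_fractions(sim$es, sim$truth, seed = 12)
  links <- sim$truth$fraction_gene_links
  tab <- immune_correlation(sim$es, fr, links$gene)
  expect_equal(nrow(tab), length(links$gene) * 22)
  expect_true(all(abs(tab$rho) <= 1))
  expect_true(all(tab$fdr >= tab$p_value - 1e-15))
  for (i in seq_len(nrow(links))) {
    row <- tab[tab$gene == links$gene[i] & tab$cell_type == links$cell_type[i], ]
    expect_gt(row$rho, 0.5)
    expect_lt(row$p_value, 0.01)
  }
  expect_error(immune_correlation(sim$es, fr[1:3, ], links$gene), "shared")
})
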