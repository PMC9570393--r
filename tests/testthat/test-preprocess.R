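test_that("quantile normalization maps columns to rank-wise means", {
  es <- make_es(matrix(c(1, 2, 3, 4, 5, 6), 3, 2),
                groups = c("DILI", "control"))
  out <- quantile_normalize(es)
  expect_equal(unname(out$exprs[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(out$exprs[, 2]), c(2.5, 3.5, 4.5))
  # original rank order preserved within a scrambled column
  es2 <- make_es(matrix(c(1, 2, 3, 6, 4, 5), 3, 2),
                 groups = c("DILI", "control"))
  out2 <- quantile_normalize(es2)
  expect_equal(unname(out2$exprs[, 2]), c(4.5, 2.5, 3.5))
})

test_that("identically distributed columns are a fixed point", {
  x <- matrix(c(1, 5, 9, 9, 1, 5, 5, 9, 1), 3, 3)
  es <- make_es(x, groups = c("DILI", "DILI", "control"))
  out <- quantile_normalize(es)
  expect_equal(out$exprs, es$exprs)
  # single column: averaging over one column changes nothing
  es1 <- make_es(matrix(c(3, 1, 2), 3, 1), groups = "DILI")
  expect_equal(quantile_normalize(es1)$exprs, es1$exprs)
})

test_that("quantile normalization is idempotent with equal column sums", {
  es <- random_es(6, 6, 80, seed = 42)
  once <- quantile_normalize(es)
  twice <- quantile_normalize(once)
  expect_equal(twice$exprs, once$exprs, tolerance = 1e-12)
  cs <- colSums(once$exprs)
  expect_lt(max(cs) - min(cs), 1e-9)
})

test_that("non-finite input is rejected with gene and sample named", {
  x <- matrix(1:6 + 0, 3, 2, dimnames = list(c("gA", "gB", "gC"), c("s1", "s2")))
  x["gB", "s2"] <- NaN
  meta <- data.frame(sample = c("s1", "s2"), group = c("DILI", "control"),
                     batch = "b1")
  expect_error(expr_set(x, meta), "gB.*s2")
})

test_that("batch adjustment removes an additive offset exactly", {
  set.seed(8)
  base <- matrix(rnorm(40 * 8, 8), 40, 8)
  x <- base
  x[, 5:8] <- x[, 5:8] + 3 # constant offset for batch 2
  es <- make_es(x, groups = rep(c("DILI", "control"), 4),
                batches = rep(c("b1", "b2"), each = 4))
  adj <- adjust_batches(es)
  m1 <- rowMeans(adj$exprs[, 1:4]); m2 <- rowMeans(adj$exprs[, 5:8])
  expect_equal(m1, m2, tolerance = 1e-9)
})

test_that("single-batch input is returned unchanged", {
  es <- random_es(4, 4, 20, seed = 9)
  expect_identical(adjust_batches(es)$exprs, es$exprs)
})

test_that("batch adjustment shrinks the batch F-statistic on simulated data", {
  # threshold measured on this seeded simulation: fraction dropped = 1
  sim <- simulate_expression(sim_config(n_genes = 300, batch_shift_sd = 2,
                                        seed = 5))
  adj <- adjust_batches(sim$es)
  b <- factor(sim$es$samples$batch)
  fstat <- function(v) summary(stats::aov(v ~ b))[[1]][1, "F value"]
  f_pre <- apply(sim$es$exprs, 1, fstat)
  f_post <- apply(adj$exprs, 1, fstat)
  expect_gte(mean(f_post < f_pre), 0.95)
})

test_that("zero within-batch variance skips scaling with a warning", {
  x <- matrix(rnorm(20), 5, 4, dimnames = list(sprintf("g%d", 1:5),
                                               sprintf("s%d", 1:4)))
  x[1, 1:2] <- 7 # constant in batch 1
  es <- make_es(x, groups = c("DILI", "DILI", "control", "control"),
                batches = c("b1", "b1", "b2", "b2"))
  expect_warning(adjust_batches(es), "zero within-batch variance")
})

test_that("stratified split reproduces the 105/27 cohort arithmetic", {
  sim <- simulate_expression(sim_config())
  sp <- split_samples(sim$es, ratio = 0.8, seed = 234)
  expect_length(sp$train_ids, 105)
  expect_length(sp$test_ids, 27)
  # per-group floor: 82 of 103 cases, 23 of 29 controls
  grp <- sim$es$samples$group[match(sp$train_ids, sim$es$samples$sample)]
  expect_equal(sum(grp == "DILI"), 82)
  expect_equal(sum(grp == "control"), 23)
})

test_that("split is an exact partition, stratified and seed-deterministic", {
  es <- random_es(10, 10, 30, seed = 12)
  sp <- split_samples(es, 0.8, 1)
  expect_length(sp$train_ids, 16)
  expect_length(sp$test_ids, 4)
  expect_length(intersect(sp$train_ids, sp$test_ids), 0)
  expect_setequal(c(sp$train_ids, sp$test_ids), es$samples$sample)
  grp <- es$samples$group[match(sp$train_ids, es$samples$sample)]
  expect_equal(unname(table(grp)["DILI"]), 8)
  sp2 <- split_samples(es, 0.8, 1)
  expect_identical(sp, sp2)
  sp3 <- split_samples(es, 0.8, 2)
  expect_false(identical(sp$train_ids, sp3$train_ids))
  expect_length(sp3$train_ids, 16)
})

test_that("per-group train fraction stays within 1/group-size of the ratio", {
  for (seed in 1:5) {
    es <- random_es(13, 7, 10, seed = seed)
    sp <- split_samples(es, 0.7, seed)
    for (g in c("DILI", "control")) {
      ids <- es$samples$sample[es$samples$group == g]
      frac <- mean(ids %in% sp$train_ids)
      expect_lte(abs(frac - 0.7), 1 / length(ids))
    }
  }
})

test_that("invalid split ratios are rejected", {
  es <- random_es(5, 5, 10, seed = 2)
  expect_error(split_samples(es, 0), "ratio")
  expect_error(split_samples(es, 1), "ratio")
})
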