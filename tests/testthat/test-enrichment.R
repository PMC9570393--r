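test_that("hypergeometric ORA matches the combinatorial examples", {
  u <- sprintf("u%02d", 1:10)
  expect_equal(ora(u[1:4], u[1:5], u), 5 / 210) # C(5,4)/C(10,4)
  expect_equal(ora(u[1:4], u, u), 1)            # annotation = universe
  expect_error(ora(c("x1"), u[1:5], u), "outside the universe")
})

test_that("ORA equals brute-force enumeration on all small instances", {
  for (n_u in c(6, 10, 15)) {
    u <- sprintf("g%02d", seq_len(n_u))
    for (seed in 1:12) {
      set.seed(seed * n_u)
      ann <- sample(u, sample(1:(n_u - 1), 1))
      hits <- sample(u, sample(1:(n_u - 1), 1))
      k <- length(intersect(hits, ann))
      expect_equal(ora(hits, ann, u),
                   brute_ora(k, n_u, length(ann), length(hits)),
                   tolerance = 1e-12)
    }
  }
})

test_that("an overlap near expectation is unremarkable", {
  u <- sprintf("g%03d", 1:100)
  # 20 hits, 50 annotated: expected overlap 10
  p <- ora(u[41:60], u[1:50], u) # overlap = 10 exactly
  expect_gt(p, 0.3); expect_lt(p, 0.8)
})

test_that("GSEA ES matches a hand-walked running sum", {
  genes <- paste0("gene", 1:6)
  scores <- c(3, 2, 1, -1, -2, -3)
  # set {gene1, gene6}: increments 3/6 and 3/6, decrements 1/4
  # running sum: .5, .25, 0, -.25, -.5, 0 -> |deviation| ties at +/-0.5;
  # the earlier extreme (+0.5) is taken
  expect_equal(gsea_es(genes, scores, c("gene1", "gene6")), 0.5)
  expect_equal(brute_gsea_es(genes, scores, c("gene1", "gene6")), 0.5)
  # top-loaded set: ES positive, equal to the increment-only prefix max
  expect_equal(gsea_es(genes, scores, c("gene1", "gene2")), 1)
  # set covering the whole list: +1 by convention
  expect_equal(gsea_es(genes, scores, genes), 1)
  expect_error(gsea_es(genes, scores, "absent"), "intersect")
  expect_error(gsea_es(c("a", "a"), c(1, 2), "a"), "duplicates")
})

test_that("GSEA ES equals brute force on random instances", {
  for (seed in 1:30) {
    set.seed(seed)
    n <- sample(10:60, 1)
    genes <- sprintf("g%03d", 1:n)
    scores <- sort(rnorm(n), decreasing = TRUE)
    gs <- sample(genes, sample(1:(n - 1), 1))
    expect_equal(gsea_es(genes, scores, gs), brute_gsea_es(genes, scores, gs),
                 tolerance = 1e-12)
  }
})

test_that("GSEA ES agrees with the reference implementation", {
  skip_if_not_installed("fgsea")
  set.seed(3)
  genes <- sprintf("g%02d", 1:50)
  scores <- sort(rnorm(50), decreasing = TRUE)
  for (k in c(3, 8, 20)) {
    gs <- sample(genes, k)
    ref <- fgsea::calcGseaStat(setNames(scores, genes),
                               which(genes %in% gs), gseaParam = 1)
    expect_equal(gsea_es(genes, scores, gs), ref, tolerance = 1e-12)
  }
})

test_that("ES flips sign when the ranking is reversed", {
  set.seed(7)
  genes <- sprintf("g%02d", 1:30)
  scores <- seq(3, -3, length.out = 30)
  gs <- genes[c(1:4, 7)]
  es_fwd <- gsea_es(genes, scores, gs)
  es_rev <- gsea_es(rev(genes), rev(scores), gs)
  expect_equal(es_rev, -es_fwd, tolerance = 1e-12)
})

test_that("permutation p is bounded below and flags a top-loaded set", {
  genes <- sprintf("g%03d", 1:100)
  scores <- sort(rnorm(100, sd = 2), decreasing = TRUE)
  p_top <- gsea_permutation_p(genes, scores, genes[1:10], n_perm = 999,
                              seed = 21)
  expect_lte(p_top, 0.01)
  expect_gte(p_top, 1 / 1000)
  expect_error(gsea_permutation_p(genes, scores, genes[1:5], n_perm = 50),
               "n_perm")
})

test_that("permutation p is roughly uniform for random sets", {
  set.seed(33)
  genes <- sprintf("g%03d", 1:80)
  scores <- sort(rnorm(80), decreasing = TRUE)
  ps <- vapply(1:30, function(i) {
    gs <- sample(genes, 8)
    gsea_permutation_p(genes, scores, gs, n_perm = 199, seed = 100 + i)
  }, numeric(1))
  expect_gt(mean(ps), 0.25)
  expect_gt(mean(ps < 0.25), 0.1) # some mass near both ends
})

test_that("GMT files round-trip through the reader", {
  path <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tfirst set\tg01\tg02\tg03",
               "setB\tsecond set\tg02\tg04"), path)
  gc <- read_gmt(path)
  expect_named(gc$sets, c("setA", "setB"))
  expect_setequal(gc$sets$setA, c("g01", "g02", "g03"))
  expect_equal(unname(gc$descriptions["setB"]), "second set")
  gc2 <- read_gmt(path, universe = c("g01", "g02", "g03"))
  expect_setequal(gc2$sets$setB, "g02")
})

test_that("enrichment_table combines ORA, ES and permutation p per set", {
  set.seed(44)
  genes <- sprintf("g%03d", 1:60)
  scores <- sort(rnorm(60), decreasing = TRUE)
  sets <- list(top = genes[1:6], random = sample(genes, 6))
  tab <- enrichment_table(genes, scores, hits = genes[1:10], sets,
                          n_perm = 199, seed = 9)
  expect_setequal(tab$set_id, c("top", "random"))
  top <- tab[tab$set_id == "top", ]
  expect_equal(top$overlap, 6)
  expect_lt(top$ora_p, 1e-4)
  expect_gt(top$es, 0.5)
  expect_lt(top$perm_p, 0.05)
  expect_true(all(tab$fdr >= tab$perm_p - 1e-15))
})
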