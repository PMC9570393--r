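# small in-code fixtures shared across test files

# a tiny ExprSet with explicit values
make_es <- function(x, groups, batches = "b1") {
  if (is.null(rownames(x))) rownames(x) <- sprintf("g%02d", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- sprintf("s%02d", seq_len(ncol(x)))
  expr_set(x, data.frame(sample = colnames(x), group = groups,
                         batch = rep_len(batches, ncol(x)),
                         stringsAsFactors = FALSE))
}

# random two-group ExprSet, n1 cases then n2 controls
random_es <- function(n1, n2, n_genes, seed, sd = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n_genes * (n1 + n2), 8, sd), n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%03d", seq_len(n1 + n2))))
  make_es(x, rep(c("DILI", "control"), c(n1, n2)))
}

# brute-force BH step-up, coded independently of bh_fdr
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    js <- which(p[o] >= p[o][i])
    adj[o[i]] <- min(1, min(m * p[o][js] / js))
  }
  adj
}

# brute-force AUC by enumerating all (case, control) pairs
brute_auc <- function(case, control) {
  s <- 0
  for (a in case) for (b in control)
    s <- s + (a > b) + 0.5 * (a == b)
  s / (length(case) * length(control))
}

# brute-force upper-tail hypergeometric via choose()
brute_ora <- function(overlap, n_universe, n_annot, n_hits) {
  ks <- overlap:min(n_annot, n_hits)
  sum(choose(n_annot, ks) * choose(n_universe - n_annot, n_hits - ks)) /
    choose(n_universe, n_hits)
}

# brute-force GSEA running sum (weight exponent 1)
brute_gsea_es <- function(genes, scores, set) {
  inset <- genes %in% set
  nr <- sum(abs(scores[inset]))
  run <- 0; best <- 0
  for (i in seq_along(genes)) {
    run <- run + if (inset[i]) abs(scores[i]) / nr else -1 / sum(!inset)
    if (abs(run) > abs(best)) best <- run
  }
  best
}
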