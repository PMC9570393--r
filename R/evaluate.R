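#' Area under the ROC curve (Mann-Whitney identity)
#'
#' AUC computed by pair counting: the fraction of (case, control) score
#' pairs with the case scored higher, ties counted 1/2. Exact and tie-robust;
#' equivalent to the normalized Wilcoxon rank-sum statistic. Orientation:
#' higher scores in cases give AUC > 0.5.
#'
#' @param scores_case,scores_control Numeric score vectors (e.g. expression
#'   of one gene in each group).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores_case, scores_control) {
  n1 <- length(scores_case); n2 <- length(scores_control)
  if (n1 == 0 || n2 == 0) stop("both groups must be non-empty")
  r <- rank(c(scores_case, scores_control))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' ROC curve points
#'
#' (FPR, TPR) pairs at every distinct score threshold, from (0,0) to (1,1),
#' for plotting; the trapezoidal area under these points equals [auc()].
#'
#' @inheritParams auc
#' @return Data frame with columns `fpr`, `tpr`, both nondecreasing.
#' @export
roc_points <- function(scores_case, scores_control) {
  if (length(scores_case) == 0 || length(scores_control) == 0)
    stop("both groups must be non-empty")
  thr <- sort(unique(c(scores_case, scores_control)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores_case >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores_control >= t), numeric(1))
  data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Two-group location test with normality gate
#'
#' Shapiro-Wilk is run on each group; if both are compatible with normality
#' (p >= 0.05) a two-sided Welch t-test is used, otherwise a two-sided
#' Wilcoxon rank-sum test. A group with zero variance (Shapiro-Wilk is
#' undefined) is treated as non-normal.
#'
#' @param values_case,values_control Numeric vectors, each of length >= 3.
#' @param force `"auto"` (default) applies the normality gate; `"t"` or
#'   `"wilcoxon"` forces that branch.
#' @return A list of class `GroupTestResult`: `statistic`, `p_value`,
#'   `test_used` (`"t"` or `"wilcoxon"`), `normality_p` (minimum of the two
#'   per-group Shapiro-Wilk p-values, `NA` if undefined).
#' @export
group_test <- function(values_case, values_control,
                       force = c("auto", "t", "wilcoxon")) {
  force <- match.arg(force)
  if (length(values_case) < 3 || length(values_control) < 3)
    stop("need >= 3 values per group for the normality check")
  shapiro_p <- function(x) {
    if (stats::sd(x) == 0) return(NA_real_)
    stats::shapiro.test(x)$p.value
  }
  p1 <- shapiro_p(values_case); p2 <- shapiro_p(values_control)
  normal <- switch(force,
                   auto = !is.na(p1) && !is.na(p2) && p1 >= 0.05 && p2 >= 0.05,
                   t = TRUE, wilcoxon = FALSE)
  if (stats::sd(c(values_case, values_control)) == 0) {
    # fully degenerate data: no evidence of a difference
    return(structure(list(statistic = NA_real_, p_value = 1,
                          test_used = "wilcoxon", normality_p = NA_real_),
                     class = "GroupTestResult"))
  }
  if (normal) {
    ht <- stats::t.test(values_case, values_control)
    used <- "t"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(values_case, values_control))
    used <- "wilcoxon"
  }
  structure(list(statistic = unname(ht$statistic), p_value = ht$p.value,
                 test_used = used, normality_p = suppressWarnings(min(p1, p2, na.rm = TRUE))),
            class = "GroupTestResult")
}

# Spearman rho: Pearson correlation of mid-ranks
spearman_rho <- function(x, y) {
  stats::cor(rank(x), rank(y))
}

#' Spearman rank correlation with p-value
#'
#' Rho is the Pearson correlation of mid-ranks. For n > 10 the two-sided
#' p-value uses the t approximation `t = rho * sqrt((n-2)/(1-rho^2))` on
#' n-2 df; for 4 <= n <= 10 it is exact, by enumerating all n! permutations
#' of one vector's ranks.
#'
#' @param x,y Numeric vectors of equal length >= 4.
#' @return List with `rho` and `p_value`.
#' @export
spearman_test <- function(x, y) {
  n <- length(x)
  if (n != length(y)) stop("x and y must have equal length")
  if (n < 4) stop("need n >= 4")
  rho <- spearman_rho(x, y)
  if (is.na(rho)) return(list(rho = NA_real_, p_value = NA_real_))
  if (n > 10) {
    if (abs(rho) >= 1) return(list(rho = rho, p_value = 0))
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    return(list(rho = rho, p_value = 2 * stats::pt(-abs(tt), df = n - 2)))
  }
  rx <- rank(x); ry <- rank(y)
  rx_c <- rx - mean(rx); ry_c <- ry - mean(ry)
  denom <- sqrt(sum(rx_c^2) * sum(ry_c^2))
  perms <- e1071::permutations(n)
  rho_perm <- (matrix(rx_c[perms], nrow(perms), n) %*% ry_c) / denom
  p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
  list(rho = rho, p_value = p)
}

#' Per-gene ROC evaluation on train and test cohorts
#'
#' @param es An [expr_set()] (normalized expression).
#' @param split A [split_samples()] result.
#' @param genes Gene ids to evaluate.
#' @return Data frame: `gene`, `cohort` (`train`/`test`), `auc`.
#' @export
evaluate_genes <- function(es, split, genes) {
  missing <- setdiff(genes, rownames(es$exprs))
  if (length(missing)) stop("unknown genes: ", paste(missing, collapse = ", "))
  cohorts <- list(train = subset_samples(es, split$train_ids),
                  test = subset_samples(es, split$test_ids))
  out <- do.call(rbind, lapply(names(cohorts), function(ch) {
    sub <- cohorts[[ch]]
    case <- is_case(sub)
    data.frame(gene = genes, cohort = ch,
               auc = vapply(genes, function(g)
                 auc(sub$exprs[g, case], sub$exprs[g, !case]), numeric(1)),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  out
}

#' Correlate selected genes with immune-cell fractions
#'
#' Spearman correlation of each gene's expression with each cell type's
#' fraction across the samples shared between the two matrices, with a
#' BH-adjusted p-value column across all (gene, cell type) pairs.
#'
#' @param es An [expr_set()].
#' @param fractions Samples x cell-types fraction matrix (rownames = sample
#'   ids), e.g. from [simulate_cell_fractions()].
#' @param genes Gene ids to correlate.
#' @return Data frame: `gene`, `cell_type`, `rho`, `p_value`, `fdr`.
#' @export
immune_correlation <- function(es, fractions, genes) {
  shared <- intersect(colnames(es$exprs), rownames(fractions))
  if (length(shared) < 4) stop("need >= 4 shared samples")
  missing <- setdiff(genes, rownames(es$exprs))
  if (length(missing)) stop("unknown genes: ", paste(missing, collapse = ", "))
  grid <- expand.grid(gene = genes, cell_type = colnames(fractions),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    spearman_test(es$exprs[grid$gene[i], shared],
                  fractions[shared, grid$cell_type[i]])
  })
  grid$rho <- vapply(res, `[[`, numeric(1), "rho")
  grid$p_value <- vapply(res, `[[`, numeric(1), "p_value")
  grid$fdr <- bh_fdr(grid$p_value)
  grid
}
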