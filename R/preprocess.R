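#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) onto the common reference distribution of
#' rank-wise means: each column is sorted, values are averaged across columns
#' at each rank, and the rank means are mapped back through each column's
#' original ordering. Tied values within a column receive the mean of the
#' rank means they span. Delegates to [limma::normalizeQuantiles()].
#'
#' @param es An [expr_set()].
#' @return An `ExprSet` with identical column distributions.
#' @export
quantile_normalize <- function(es) {
  if (!all(is.finite(es$exprs))) {
    bad <- which(!is.finite(es$exprs), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite value at gene '%s', sample '%s'",
                 rownames(es$exprs)[bad[1]], colnames(es$exprs)[bad[2]]))
  }
  out <- limma::normalizeQuantiles(es$exprs, ties = TRUE)
  dimnames(out) <- dimnames(es$exprs)
  expr_set(out, es$samples, es$case_level, es$control_level)
}

#' Adjust additive batch effects
#'
#' Per gene, each batch's values are centered and scaled to unit variance,
#' then rescaled to the gene's pooled mean and pooled variance. This removes
#' additive (location) and multiplicative (scale) batch effects; it is the
#' non-shrinkage core of location/scale batch correction. A single-batch
#' input is returned unchanged. A (gene, batch) cell with zero within-batch
#' variance keeps its scale and is only re-centered (a warning reports how
#' many cells were affected).
#'
#' @param es An [expr_set()] whose `samples$batch` defines the batches.
#' @return A batch-adjusted `ExprSet`.
#' @export
adjust_batches <- function(es) {
  batch <- as.character(es$samples$batch)
  ub <- unique(batch)
  if (length(ub) < 2) return(es)
  sizes <- table(batch)
  if (any(sizes < 2))
    stop("each batch needs >= 2 samples; too small: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  x <- es$exprs
  pooled_mean <- rowMeans(x)
  pooled_sd <- apply(x, 1, stats::sd)
  out <- x
  n_degenerate <- 0L
  for (b in ub) {
    cols <- batch == b
    xb <- x[, cols, drop = FALSE]
    mb <- rowMeans(xb)
    sb <- apply(xb, 1, stats::sd)
    zero <- sb == 0
    n_degenerate <- n_degenerate + sum(zero)
    scale_fac <- ifelse(zero, 1, pooled_sd / sb)
    out[, cols] <- (xb - mb) * scale_fac + pooled_mean
  }
  if (n_degenerate > 0)
    warning(n_degenerate, " (gene, batch) cells had zero within-batch ",
            "variance; scale adjustment skipped for those cells")
  expr_set(out, es$samples, es$case_level, es$control_level)
}

#' Stratified train/test split
#'
#' Draws a seeded random split, stratified by group: within each group,
#' `floor(ratio * group size)` samples go to the training set and the
#' remainder to the test set. With 103 cases and 29 controls at ratio 0.8
#' this yields the 105-train / 27-test totals of the cohort the pipeline
#' emulates.
#'
#' @param es An [expr_set()].
#' @param ratio Training fraction, in (0, 1). Default 0.8.
#' @param seed Integer seed (default 234).
#' @return A list of class `SampleSplit`: `train_ids`, `test_ids`, `ratio`,
#'   `seed`.
#' @export
split_samples <- function(es, ratio = 0.8, seed = 234) {
  if (!is.numeric(ratio) || length(ratio) != 1 || ratio <= 0 || ratio >= 1)
    stop("`ratio` must be in (0, 1)")
  groups <- split(es$samples$sample, es$samples$group)
  if (any(lengths(groups) < 2))
    stop("need >= 2 samples per group")
  set.seed(as.integer(seed))
  train <- character(0)
  for (g in sort(names(groups))) {
    ids <- groups[[g]]
    k <- floor(ratio * length(ids))
    train <- c(train, sample(ids, k))
  }
  all_ids <- es$samples$sample
  structure(list(train_ids = all_ids[all_ids %in% train],
                 test_ids = all_ids[!all_ids %in% train],
                 ratio = ratio, seed = as.integer(seed)),
            class = "SampleSplit")
}

#' @export
print.SampleSplit <- function(x, ...) {
  cat(sprintf("SampleSplit: %d train / %d test (ratio %.2f, seed %d)\n",
              length(x$train_ids), length(x$test_ids), x$ratio, x$seed))
  invisible(x)
}
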