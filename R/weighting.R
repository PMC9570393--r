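#' Normalize and aggregate model importances
#'
#' The pipeline's central statistic. Each model's raw importances are taken
#' in absolute value and divided by the model's maximum absolute importance,
#' so every model contributes on a common `[0, 1]` scale with its top gene at
#' exactly 1; the overall weight of a gene is the sum of its normalized
#' weights across models:
#' \deqn{W_g = \sum_{m} |w_{g,m}| / \max_{g'} |w_{g',m}|.}
#' A model whose importances are all zero (e.g. a lasso that selected
#' nothing) contributes a zero column rather than 0/0.
#'
#' @param vectors List of `ImportanceVector`s from [fit_model()] /
#'   [fit_all_models()], or a named list of named numeric vectors. All must
#'   cover the same gene universe.
#' @param models Optional model-column order; defaults to
#'   `lasso, svm, rf, nn, gbm, dt` order when the canonical six are present,
#'   otherwise the input order.
#' @return A data frame of class `WeightTable`: `gene`, one normalized column
#'   per model, and `total`, ordered by `total` descending then gene id.
#' @export
normalize_importances <- function(vectors, models = NULL) {
  if (length(vectors) == 0) stop("no importance vectors supplied")
  raws <- lapply(vectors, function(v) if (inherits(v, "ImportanceVector")) v$raw else v)
  if (is.null(names(raws)) || any(names(raws) == ""))
    names(raws) <- vapply(vectors, function(v)
      if (inherits(v, "ImportanceVector")) v$model else stop("unnamed vector"),
      character(1))
  genes <- names(raws[[1]])
  for (m in names(raws)) {
    if (!setequal(names(raws[[m]]), genes)) {
      diff <- c(setdiff(genes, names(raws[[m]])), setdiff(names(raws[[m]]), genes))
      stop("gene universes differ (model '", m, "'): ",
           paste(unique(diff), collapse = ", "))
    }
    if (any(!is.finite(raws[[m]])) ) stop("non-finite importance in model '", m, "'")
  }
  canonical <- c("lasso", "svm_linear", "random_forest", "neural_net", "gbm",
                 "decision_tree")
  if (is.null(models)) {
    models <- if (setequal(names(raws), canonical)) canonical else names(raws)
  }
  norm <- vapply(models, function(m) {
    a <- abs(raws[[m]][genes])
    mx <- max(a)
    if (mx == 0) a else a / mx
  }, numeric(length(genes)))
  norm <- matrix(norm, nrow = length(genes),
                 dimnames = list(genes, models))
  out <- data.frame(gene = genes, norm, total = rowSums(norm),
                    row.names = NULL, check.names = FALSE,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$total, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("WeightTable", "data.frame")
  out
}

#' Select diagnostic genes by overall weight
#'
#' Returns genes whose overall weight exceeds `threshold` (strictly), sorted
#' by weight descending and gene id ascending on ties. The default threshold
#' of 3 — half the attainable maximum of 6 — selects genes that carry, on
#' average, at least half the maximum weight per model.
#'
#' @param table A `WeightTable` from [normalize_importances()].
#' @param threshold Strict lower bound on the overall weight (default 3).
#' @return Character vector of selected gene ids.
#' @export
select_genes <- function(table, threshold = 3) {
  sel <- table[table$total > threshold, , drop = FALSE]
  sel <- sel[order(-sel$total, sel$gene), , drop = FALSE]
  sel$gene
}
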