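#' Expression set container
#'
#' Lightweight container for a log2 gene-by-sample expression matrix plus
#' per-sample annotation, in the spirit of limma's `EList`. Every downstream
#' stage of the pipeline (normalization, batch adjustment, differential
#' expression, classifier training, evaluation) operates on this object.
#'
#' @param exprs Numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids). Values are log2 intensities.
#' @param samples Data frame with columns `sample`, `group`, `batch`; one row
#'   per column of `exprs`, in the same order.
#' @param case_level Value of `group` identifying cases (default `"DILI"`).
#' @param control_level Value of `group` identifying controls.
#'
#' @return An object of class `ExprSet`: a list with elements `exprs`,
#'   `samples`, `case_level`, `control_level`.
#' @export
expr_set <- function(exprs, samples, case_level = "DILI",
                     control_level = "control") {
  if (!is.matrix(exprs) || !is.numeric(exprs))
    stop("`exprs` must be a numeric matrix")
  if (is.null(rownames(exprs)) || is.null(colnames(exprs)))
    stop("`exprs` must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(exprs)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(exprs)[duplicated(rownames(exprs))]),
               collapse = ", "))
  if (anyDuplicated(colnames(exprs)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(exprs)[duplicated(colnames(exprs))]),
               collapse = ", "))
  if (!all(is.finite(exprs))) {
    bad <- which(!is.finite(exprs), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite expression value at gene '%s', sample '%s'",
                 rownames(exprs)[bad[1]], colnames(exprs)[bad[2]]))
  }
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  need <- c("sample", "group", "batch")
  if (!all(need %in% names(samples)))
    stop("`samples` must have columns: ", paste(need, collapse = ", "))
  if (!identical(as.character(samples$sample), colnames(exprs)))
    stop("`samples$sample` must match colnames(exprs) in order")
  if (!all(samples$group %in% c(case_level, control_level)))
    stop("`samples$group` must be one of '", case_level, "', '",
         control_level, "'")
  structure(list(exprs = exprs, samples = samples,
                 case_level = case_level, control_level = control_level),
            class = "ExprSet")
}

#' @export
print.ExprSet <- function(x, ...) {
  cat(sprintf("ExprSet: %d genes x %d samples (%d %s, %d %s; %d batches)\n",
              nrow(x$exprs), ncol(x$exprs),
              sum(x$samples$group == x$case_level), x$case_level,
              sum(x$samples$group == x$control_level), x$control_level,
              length(unique(x$samples$batch))))
  invisible(x)
}

#' @export
dim.ExprSet <- function(x) dim(x$exprs)

# logical mask of case samples, in column order
is_case <- function(es) es$samples$group == es$case_level

# subset an ExprSet by sample ids, preserving order of `ids`
subset_samples <- function(es, ids) {
  idx <- match(ids, colnames(es$exprs))
  if (anyNA(idx)) stop("unknown sample ids: ",
                       paste(ids[is.na(idx)], collapse = ", "))
  expr_set(es$exprs[, idx, drop = FALSE], es$samples[idx, , drop = FALSE],
           case_level = es$case_level, control_level = es$control_level)
}
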