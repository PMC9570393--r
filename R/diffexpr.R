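#' DEG filtering criteria
#'
#' @param logfc_threshold Minimum |log2 fold change| (strict), default 0.8.
#' @param fdr_threshold Maximum BH-adjusted p (strict), default 0.05.
#' @param p_threshold Maximum raw p (strict), default 0.05. Redundant given
#'   the FDR cut (adjusted p >= raw p) but applied literally.
#' @return A list of class `DegCriteria`.
#' @export
deg_criteria <- function(logfc_threshold = 0.8, fdr_threshold = 0.05,
                         p_threshold = 0.05) {
  if (logfc_threshold <= 0) stop("`logfc_threshold` must be > 0")
  if (fdr_threshold <= 0 || fdr_threshold > 1) stop("`fdr_threshold` must be in (0, 1]")
  if (p_threshold <= 0 || p_threshold > 1) stop("`p_threshold` must be in (0, 1]")
  structure(list(logfc_threshold = logfc_threshold,
                 fdr_threshold = fdr_threshold, p_threshold = p_threshold),
            class = "DegCriteria")
}

# Newton inversion of the trigamma function (for the prior df estimator)
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Empirical-Bayes moderated t-test
#'
#' Per-gene two-group comparison on the training samples. The log2 fold
#' change is the case-mean minus control-mean. Each gene's pooled residual
#' variance \eqn{s_g^2} (with \eqn{d_g = n_1 + n_2 - 2} df) is shrunk toward
#' a prior \eqn{(d_0, s_0^2)} estimated by matching the first two moments of
#' \eqn{\log s_g^2} under a scaled-F model; the moderated statistic is
#' \deqn{\tilde t_g = \mathrm{logFC}_g / (\tilde s_g \sqrt{1/n_1 + 1/n_2}),
#'   \quad \tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g),}
#' with two-sided p-values on \eqn{d_0 + d_g} df. An infinite \eqn{d_0}
#' shrinks fully to \eqn{s_0^2} (normal reference); if the prior cannot be
#' estimated the function falls back to the ordinary pooled t
#' (\eqn{d_0 = 0}) with a warning. BH-adjusted p-values are included.
#'
#' @param es An [expr_set()].
#' @param split Optional [split_samples()] result; if supplied only
#'   `train_ids` are used.
#' @param d0 Optional prior df override; `0` forces the ordinary pooled
#'   two-sample t, `Inf` shrinks fully to the prior variance.
#' @return A data frame (one row per gene): `gene`, `logfc`, `t_stat`,
#'   `p_value`, `fdr`; attributes `d0` and `s0_sq` record the fitted prior.
#' @export
moderated_t <- function(es, split = NULL, d0 = NULL) {
  if (!is.null(split)) es <- subset_samples(es, split$train_ids)
  case <- is_case(es)
  n1 <- sum(case); n2 <- sum(!case)
  if (n1 < 2 || n2 < 2) stop("need >= 2 samples per group")
  x1 <- es$exprs[, case, drop = FALSE]
  x2 <- es$exprs[, !case, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  logfc <- m1 - m2
  dg <- n1 + n2 - 2
  s2 <- (rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)) / dg
  if (all(s2 == 0)) stop("zero variance in both groups for every gene")

  if (is.null(d0)) {
    ok <- s2 > 0
    e <- log(s2[ok]) - digamma(dg / 2) + log(dg / 2)
    emean <- mean(e)
    evar <- sum((e - emean)^2) / (length(e) - 1) - trigamma(dg / 2)
    if (!is.finite(evar)) {
      warning("prior df estimation failed; falling back to ordinary t (d0 = 0)")
      d0 <- 0; s0_sq <- NA_real_
    } else if (evar <= 0) {
      d0 <- Inf
      s0_sq <- exp(emean)
    } else {
      d0 <- 2 * trigamma_inverse(evar)
      s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    }
  } else {
    s0_sq <- if (is.infinite(d0)) exp(mean(log(s2[s2 > 0]))) else mean(s2)
  }

  if (d0 == 0) {
    s2_post <- s2
  } else if (is.infinite(d0)) {
    s2_post <- rep(s0_sq, length(s2))
  } else {
    s2_post <- (d0 * s0_sq + dg * s2) / (d0 + dg)
  }
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t_stat <- ifelse(logfc == 0, 0, logfc / se)
  df_total <- d0 + dg
  p <- 2 * stats::pt(-abs(t_stat), df = df_total)
  p[logfc == 0] <- 1
  out <- data.frame(gene = rownames(es$exprs), logfc = logfc, t_stat = t_stat,
                    p_value = p, fdr = bh_fdr(p), row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "d0") <- d0
  attr(out, "s0_sq") <- s0_sq
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `adj_(i) = min_{j >= i} m * p_(j) / j`, capped at
#' 1 and mapped back to input order (via [stats::p.adjust()]).
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
bh_fdr <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must be in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Filter differentially expressed genes
#'
#' Applies the three-criterion filter — `|logfc| > logfc_threshold`,
#' `fdr < fdr_threshold`, `p < p_threshold`, all strict — and returns the
#' passing genes ordered by decreasing `|t_stat|`.
#'
#' @param records Data frame from [moderated_t()].
#' @param criteria A [deg_criteria()] object.
#' @return The `records` rows flagged `passes = TRUE`, ordered by `|t_stat|`
#'   descending; the full annotated table is attached as attribute `"all"`.
#' @export
filter_degs <- function(records, criteria = deg_criteria()) {
  records$passes <- abs(records$logfc) > criteria$logfc_threshold &
    records$fdr < criteria$fdr_threshold &
    records$p_value < criteria$p_threshold
  degs <- records[records$passes, , drop = FALSE]
  degs <- degs[order(-abs(degs$t_stat), degs$gene), , drop = FALSE]
  rownames(degs) <- NULL
  attr(degs, "all") <- records
  degs
}
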