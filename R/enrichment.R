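#' Read a GMT gene-set file
#'
#' Standard GMT dialect: one set per line, tab-separated — set id,
#' description, then member gene ids.
#'
#' @param path Path to a `.gmt` file.
#' @param universe Optional gene universe; sets are intersected with it and
#'   sets left empty are dropped.
#' @return A list of class `GeneSetCollection`: `sets` (named list of
#'   character vectors), `descriptions` (named character), `universe`.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(ids))
    stop("duplicate set ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  desc <- vapply(parts, function(p) if (length(p) >= 2) p[2] else "", character(1))
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  names(sets) <- ids; names(desc) <- ids
  if (!is.null(universe)) {
    sets <- lapply(sets, intersect, y = universe)
    keep <- lengths(sets) > 0
    sets <- sets[keep]; desc <- desc[keep]
  }
  structure(list(sets = sets, descriptions = desc, universe = universe),
            class = "GeneSetCollection")
}

#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability of observing at least the actual overlap between a
#' hit list and an annotated set, drawing `|hits|` genes without replacement
#' from a universe containing `|annotation|` annotated genes.
#'
#' @param hits Character vector of hit genes (e.g. DEGs); must lie in
#'   `universe`.
#' @param annotation Character vector, the gene set; must lie in `universe`.
#' @param universe Character vector, the background gene universe.
#' @return `P(X >= overlap)` from the hypergeometric distribution.
#' @export
ora <- function(hits, annotation, universe) {
  if (!all(hits %in% universe))
    stop("hits outside the universe: ",
         paste(setdiff(hits, universe), collapse = ", "))
  if (!all(annotation %in% universe))
    stop("annotation outside the universe: ",
         paste(setdiff(annotation, universe), collapse = ", "))
  hits <- unique(hits); annotation <- unique(annotation)
  universe <- unique(universe)
  k <- length(intersect(hits, annotation))
  stats::phyper(k - 1, length(annotation),
                length(universe) - length(annotation), length(hits),
                lower.tail = FALSE)
}

#' GSEA enrichment score (weighted running sum)
#'
#' Walks the ranked list from top to bottom; at an in-set gene the running
#' sum increases by `|score|^exponent` normalized over the in-set genes, at
#' an out-of-set gene it decreases by `1/(N - Nh)`. The enrichment score is
#' the signed maximum deviation from zero. If the set covers the whole list
#' the decrement pool is empty and the ES is `+1` by convention.
#'
#' @param ranked_genes Character vector of gene ids, ordered by decreasing
#'   score; no duplicates.
#' @param scores Numeric scores aligned with `ranked_genes` (the ranking
#'   metric, e.g. the moderated t).
#' @param gene_set Character vector; must intersect `ranked_genes`.
#' @param exponent Weight exponent on `|score|` (default 1, classic GSEA).
#' @return The enrichment score, in `[-1, 1]`.
#' @export
gsea_es <- function(ranked_genes, scores, gene_set, exponent = 1) {
  if (anyDuplicated(ranked_genes)) stop("ranked list contains duplicates")
  if (length(scores) != length(ranked_genes))
    stop("`scores` must align with `ranked_genes`")
  inset <- ranked_genes %in% gene_set
  nh <- sum(inset)
  if (nh == 0) stop("gene set does not intersect the ranked list")
  n <- length(ranked_genes)
  if (nh == n) return(1)
  w <- abs(scores)^exponent
  nr <- sum(w[inset])
  step <- ifelse(inset,
                 if (nr > 0) w / nr else 1 / nh, # all-zero scores: flat weights
                 -1 / (n - nh))
  if (nr == 0) step[inset] <- 1 / nh
  running <- cumsum(step)
  running[which.max(abs(running))]
}

#' Permutation p-value for a GSEA enrichment score
#'
#' Gene-label permutation null: the set's positions in the ranked list are
#' redrawn uniformly `n_perm` times and the two-sided p-value is
#' `(1 + #{|ES*| >= |ES|}) / (n_perm + 1)`.
#'
#' @inheritParams gsea_es
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @return Permutation p-value in `(0, 1]`.
#' @export
gsea_permutation_p <- function(ranked_genes, scores, gene_set,
                               n_perm = 999, seed = 234, exponent = 1) {
  if (n_perm < 100) stop("`n_perm` must be >= 100")
  es_obs <- gsea_es(ranked_genes, scores, gene_set, exponent)
  nh <- sum(ranked_genes %in% gene_set)
  set.seed(as.integer(seed))
  hits <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(length(ranked_genes), nh)
    abs(gsea_es(ranked_genes, scores, ranked_genes[idx], exponent)) >=
      abs(es_obs) - 1e-12
  }, logical(1))
  (1 + sum(hits)) / (n_perm + 1)
}

#' Enrichment table over a gene-set collection
#'
#' For each set: the ORA hypergeometric p for the overlap between `hits` and
#' the set, the GSEA enrichment score along the ranked list, its permutation
#' p, and BH-adjusted permutation p-values across sets.
#'
#' @param ranked_genes,scores Ranked gene list (decreasing score) and the
#'   aligned scores.
#' @param hits Hit list for the ORA component (e.g. the DEGs).
#' @param collection A [read_gmt()] `GeneSetCollection` (or named list of
#'   character vectors).
#' @param n_perm,seed Permutation settings for [gsea_permutation_p()].
#' @return Data frame: `set_id`, `overlap`, `ora_p`, `es`, `perm_p`, `fdr`.
#' @export
enrichment_table <- function(ranked_genes, scores, hits, collection,
                             n_perm = 999, seed = 234) {
  sets <- if (inherits(collection, "GeneSetCollection")) collection$sets
          else collection
  universe <- ranked_genes
  hits <- intersect(hits, universe)
  rows <- lapply(names(sets), function(id) {
    gs <- intersect(sets[[id]], universe)
    if (length(gs) == 0) return(NULL)
    data.frame(set_id = id, overlap = length(intersect(hits, gs)),
               ora_p = ora(hits, gs, universe),
               es = gsea_es(ranked_genes, scores, gs),
               perm_p = gsea_permutation_p(ranked_genes, scores, gs,
                                           n_perm = n_perm, seed = seed),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no gene set intersects the ranked list")
  out$fdr <- bh_fdr(out$perm_p)
  out[order(out$perm_p, out$set_id), , drop = FALSE]
}
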