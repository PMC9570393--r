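#' Simulation configuration
#'
#' Parameters of the synthetic microarray generator. The defaults emulate the
#' cohort structure the pipeline was designed around: 103 cases vs 29
#' controls pooled from six array batches, a few thousand genes on the log2
#' scale, and a small set of planted upregulated genes with log2 fold changes
#' between 1 and 2 (one dominant marker at 2.0).
#'
#' @param n_case,n_control Number of case / control samples.
#' @param n_genes Total number of genes.
#' @param n_de Number of planted differentially expressed genes.
#' @param logfc_values Numeric vector of length `n_de`: planted log2 fold
#'   changes (case minus control). Positive values mean upregulation in cases.
#' @param n_batches Number of array batches; samples are assigned round-robin.
#' @param batch_shift_sd SD of the per-(batch, gene) additive offset (log2
#'   units).
#' @param noise_sd Per-observation Gaussian noise SD (log2 units).
#' @param baseline_mean,baseline_sd Mean and SD of per-gene baseline log2
#'   expression.
#' @param n_cell_types Number of immune cell types in the companion
#'   cell-fraction simulator (default 22).
#' @param seed Integer seed; all randomness in [simulate_expression()] flows
#'   from it.
#'
#' @return A list of class `SimConfig`.
#' @export
sim_config <- function(n_case = 103, n_control = 29, n_genes = 2000,
                       n_de = 20,
                       logfc_values = c(2, seq(1, 1.5, length.out = n_de - 1)),
                       n_batches = 6, batch_shift_sd = 0.5, noise_sd = 0.5,
                       baseline_mean = 8, baseline_sd = 1.5,
                       n_cell_types = 22, seed = 234) {
  cfg <- list(n_case = n_case, n_control = n_control, n_genes = n_genes,
              n_de = n_de, logfc_values = if (n_de > 0) logfc_values else numeric(0),
              n_batches = n_batches, batch_shift_sd = batch_shift_sd,
              noise_sd = noise_sd, baseline_mean = baseline_mean,
              baseline_sd = baseline_sd, n_cell_types = n_cell_types,
              seed = as.integer(seed))
  counts <- c("n_case", "n_control", "n_genes", "n_batches", "n_cell_types")
  for (nm in counts)
    if (length(cfg[[nm]]) != 1 || cfg[[nm]] < 1 || cfg[[nm]] != round(cfg[[nm]]))
      stop("`", nm, "` must be a positive integer")
  if (cfg$n_de < 0 || cfg$n_de > cfg$n_genes)
    stop("`n_de` must be in [0, n_genes]")
  if (length(cfg$logfc_values) != cfg$n_de)
    stop("`logfc_values` must have length n_de")
  if (cfg$noise_sd <= 0) stop("`noise_sd` must be > 0")
  if (cfg$batch_shift_sd < 0) stop("`batch_shift_sd` must be >= 0")
  class(cfg) <- "SimConfig"
  cfg
}

#' Simulate a synthetic microarray cohort
#'
#' Draws a genes-by-samples log2 expression matrix under an additive Gaussian
#' model: per-gene baseline + per-(batch, gene) offset + planted case effect
#' + observation noise. Batches are assigned round-robin over samples, so
#' batch is approximately balanced across the two groups and the batch signal
#' is separable from the group signal.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `es` (an [expr_set()]) and `truth` (class
#'   `SimTruth`: `de_gene_ids`, `true_logfc` named vector, and
#'   `fraction_gene_links`, a data frame of planted gene/cell-type
#'   association strengths used by [simulate_cell_fractions()]).
#' @export
simulate_expression <- function(config) {
  if (!inherits(config, "SimConfig")) config <- do.call(sim_config, config)
  set.seed(config$seed)
  n <- config$n_case + config$n_control
  gene_ids <- sprintf("GENE%04d", seq_len(config$n_genes))
  sample_ids <- c(sprintf("DILI_%03d", seq_len(config$n_case)),
                  sprintf("CTRL_%03d", seq_len(config$n_control)))
  group <- rep(c("DILI", "control"), c(config$n_case, config$n_control))
  batch <- sprintf("batch%d", ((seq_len(n) - 1) %% config$n_batches) + 1)

  de_idx <- if (config$n_de > 0) sample.int(config$n_genes, config$n_de) else integer(0)
  true_logfc <- stats::setNames(config$logfc_values, gene_ids[de_idx])

  baseline <- stats::rnorm(config$n_genes, config$baseline_mean, config$baseline_sd)
  batch_offset <- matrix(stats::rnorm(config$n_genes * config$n_batches,
                                      0, config$batch_shift_sd),
                         config$n_genes, config$n_batches,
                         dimnames = list(NULL, sprintf("batch%d", seq_len(config$n_batches))))
  effect <- numeric(config$n_genes)
  effect[de_idx] <- config$logfc_values

  x <- matrix(stats::rnorm(config$n_genes * n, 0, config$noise_sd),
              config$n_genes, n, dimnames = list(gene_ids, sample_ids))
  x <- x + baseline
  x <- x + batch_offset[, batch, drop = FALSE]
  x[, group == "DILI"] <- x[, group == "DILI"] + effect

  # link the first few planted genes to distinct cell types so downstream
  # Spearman tests have a known sign
  n_links <- min(4, config$n_de, config$n_cell_types)
  links <- data.frame(gene = gene_ids[de_idx][seq_len(n_links)],
                      cell_type = sprintf("cell_type_%02d", seq_len(n_links)),
                      strength = rep(1, n_links),
                      stringsAsFactors = FALSE)
  if (n_links == 0) links <- links[0, ]

  truth <- structure(list(de_gene_ids = gene_ids[de_idx],
                          true_logfc = true_logfc,
                          fraction_gene_links = links,
                          n_cell_types = config$n_cell_types),
                     class = "SimTruth")
  es <- expr_set(x, data.frame(sample = sample_ids, group = group,
                               batch = batch, stringsAsFactors = FALSE))
  list(es = es, truth = truth)
}

#' Simulate immune cell fractions
#'
#' Generates a samples-by-cell-types fraction matrix on the unit simplex
#' (Dirichlet-style: normalized gamma draws). For every planted
#' (gene, cell type) link in `truth`, the corresponding cell type's
#' concentration parameter is scaled by `exp(strength * z)` where `z` is the
#' gene's standardized expression, so the fraction is (noisily) monotone in
#' expression and its Spearman correlation has a known sign.
#'
#' @param es An [expr_set()].
#' @param truth A `SimTruth` from [simulate_expression()] (or `NULL` for a
#'   link-free null panel).
#' @param seed Integer seed.
#' @param concentration Baseline Dirichlet concentration per cell type.
#' @return Numeric matrix, samples x cell types; rows sum to 1.
#' @export
simulate_cell_fractions <- function(es, truth = NULL, seed = 234,
                                    concentration = 2) {
  if (ncol(es$exprs) < 1) stop("need at least one sample")
  set.seed(as.integer(seed))
  n_cell <- if (!is.null(truth)) truth$n_cell_types else 22
  samples <- colnames(es$exprs)
  alpha <- matrix(concentration, length(samples), n_cell,
                  dimnames = list(samples, sprintf("cell_type_%02d", seq_len(n_cell))))
  links <- if (!is.null(truth)) truth$fraction_gene_links else NULL
  if (!is.null(links) && nrow(links) > 0) {
    for (i in seq_len(nrow(links))) {
      g <- links$gene[i]; ct <- links$cell_type[i]
      z <- as.numeric(scale(es$exprs[g, ]))
      alpha[, ct] <- alpha[, ct] * exp(links$strength[i] * z)
    }
  }
  draws <- matrix(stats::rgamma(length(alpha), shape = alpha, rate = 1),
                  nrow(alpha), ncol(alpha), dimnames = dimnames(alpha))
  draws / rowSums(draws)
}
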