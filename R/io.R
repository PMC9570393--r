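#' Read an expression matrix from TSV
#'
#' Expected dialect: header row of sample ids, first column gene ids,
#' remaining columns numeric log2 values.
#'
#' @param expr_path Path to the expression TSV.
#' @param meta_path Optional path to a metadata TSV with columns `sample`,
#'   `group`, `batch`; required to build a full [expr_set()].
#' @param case_level,control_level Group labels (defaults `"DILI"`,
#'   `"control"`).
#' @return An `ExprSet` if `meta_path` is given, otherwise the bare numeric
#'   matrix.
#' @export
read_expression <- function(expr_path, meta_path = NULL,
                            case_level = "DILI", control_level = "control") {
  df <- utils::read.delim(expr_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  gene_ids <- as.character(df[[1]])
  if (anyDuplicated(gene_ids))
    stop("duplicate gene id(s) in ", expr_path, ": ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(vals[[j]]))))[1]
      stop(sprintf("non-numeric value at gene '%s', sample '%s'",
                   gene_ids[bad], names(vals)[j]))
    }
  }
  x <- as.matrix(vals)
  rownames(x) <- gene_ids
  if (is.null(meta_path)) return(x)
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  meta <- meta[match(colnames(x), meta$sample), , drop = FALSE]
  expr_set(x, meta, case_level, control_level)
}

#' Write an expression matrix (and metadata) as TSV
#'
#' @param es An [expr_set()] or numeric matrix.
#' @param expr_path Output path for the expression TSV (first column `gene`).
#' @param meta_path Optional output path for the sample metadata TSV.
#' @export
write_expression <- function(es, expr_path, meta_path = NULL) {
  x <- if (inherits(es, "ExprSet")) es$exprs else es
  # %.17g so that read.delim recovers bit-identical doubles
  df <- data.frame(gene = rownames(x),
                   apply(x, 2, function(col) sprintf("%.17g", col)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene", colnames(x))
  utils::write.table(df, expr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(meta_path) && inherits(es, "ExprSet"))
    utils::write.table(es$samples, meta_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(expr_path)
}

#' Read/write a sample split as JSON
#'
#' @param split A `SampleSplit`.
#' @param path JSON path.
#' @export
write_split <- function(split, path) {
  jsonlite::write_json(list(train = split$train_ids, test = split$test_ids,
                            ratio = split$ratio, seed = split$seed),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(train_ids = x$train, test_ids = x$test, ratio = x$ratio,
                 seed = as.integer(x$seed)), class = "SampleSplit")
}

#' Pipeline configuration
#'
#' @param sim A [sim_config()] (used when no expression input is given).
#' @param ratio,seed Split ratio and pipeline seed.
#' @param criteria A [deg_criteria()].
#' @param weight_threshold Overall-weight selection cutoff (default 3).
#' @param model_specs Optional named list of [model_spec()] overrides.
#' @param gmt Optional path to a GMT file for the enrichment stage.
#' @param out_dir Optional output directory; if given, every stage's
#'   artifact is written there.
#' @return A list of class `PipelineConfig`.
#' @export
pipeline_config <- function(sim = sim_config(), ratio = 0.8, seed = 234,
                            criteria = deg_criteria(), weight_threshold = 3,
                            model_specs = NULL, gmt = NULL, out_dir = NULL) {
  structure(list(sim = sim, ratio = ratio, seed = as.integer(seed),
                 criteria = criteria, weight_threshold = weight_threshold,
                 model_specs = model_specs, gmt = gmt, out_dir = out_dir),
            class = "PipelineConfig")
}

#' Run the full biomarker-discovery pipeline
#'
#' Stages: simulate (or take) an expression cohort, quantile-normalize,
#' adjust batches, split 80:20 stratified, moderated-t differential
#' expression with the three-criterion filter, fit the six-classifier
#' ensemble on the DEG features, normalize and sum importances, select genes
#' above the overall-weight threshold, evaluate per-gene ROC/AUC on both
#' cohorts and group differences on the test cohort, correlate selected
#' genes with simulated immune fractions, and (optionally, if a GMT is
#' supplied) compute enrichment statistics over the DEG-ranked list.
#'
#' @param config A [pipeline_config()].
#' @param es Optional [expr_set()]; if `NULL`, data are simulated from
#'   `config$sim`.
#' @param fractions Optional samples x cell-types matrix; if `NULL` and data
#'   are simulated, fractions are simulated too.
#' @return A list of class `PipelineResult` with elements `es`, `split`,
#'   `deg_table`, `degs`, `importances`, `weight_table`, `selected_genes`,
#'   `auc_table`, `group_tests`, `immune_cor`, `enrichment`, `summary`.
#' @export
run_pipeline <- function(config = pipeline_config(), es = NULL,
                         fractions = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  truth <- NULL
  if (is.null(es)) {
    sim <- stage("simulate", {
      cfg <- config$sim; cfg$seed <- config$seed
      simulate_expression(cfg)
    })
    es <- sim$es
    truth <- sim$truth
    if (is.null(fractions))
      fractions <- stage("simulate_fractions",
                         simulate_cell_fractions(es, truth, seed = config$seed + 1))
  }
  es_norm <- stage("quantile_normalize", quantile_normalize(es))
  es_adj <- stage("adjust_batches", adjust_batches(es_norm))
  split <- stage("split", split_samples(es_adj, config$ratio, config$seed))
  deg_table <- stage("diffexpr", moderated_t(es_adj, split))
  degs <- stage("filter_degs", filter_degs(deg_table, config$criteria))
  if (nrow(degs) == 0)
    stop("pipeline stage 'filter_degs': no gene passed the DEG criteria")
  imps <- stage("ensemble",
                fit_all_models(es_adj, split, degs$gene, seed = config$seed,
                               specs = config$model_specs))
  wt <- stage("weighting", normalize_importances(imps))
  selected <- stage("select", select_genes(wt, config$weight_threshold))
  auc_tab <- if (length(selected))
    stage("evaluate", evaluate_genes(es_adj, split, selected)) else NULL
  gtests <- if (length(selected)) stage("group_tests", {
    te <- subset_samples(es_adj, split$test_ids)
    case <- is_case(te)
    do.call(rbind, lapply(selected, function(g) {
      r <- group_test(te$exprs[g, case], te$exprs[g, !case])
      data.frame(gene = g, statistic = r$statistic, p_value = r$p_value,
                 test_used = r$test_used, stringsAsFactors = FALSE)
    }))
  }) else NULL
  icor <- if (length(selected) && !is.null(fractions))
    stage("immune_correlation", immune_correlation(es_adj, fractions, selected))
  else NULL
  enr <- if (!is.null(config$gmt)) stage("enrichment", {
    ord <- order(-deg_table$t_stat)
    enrichment_table(deg_table$gene[ord], deg_table$t_stat[ord], degs$gene,
                     read_gmt(config$gmt), seed = config$seed)
  }) else NULL

  summary <- list(
    n_genes = nrow(es$exprs), n_samples = ncol(es$exprs),
    n_train = length(split$train_ids), n_test = length(split$test_ids),
    n_degs = nrow(degs),
    model_errors = lapply(imps, function(v)
      list(train = v$train_error, test = v$test_error)),
    selected_genes = selected,
    auc = if (!is.null(auc_tab))
      lapply(split(auc_tab, auc_tab$gene), function(d)
        stats::setNames(as.list(d$auc), d$cohort)) else list(),
    weight_threshold = config$weight_threshold, seed = config$seed)

  res <- structure(list(es = es_adj, split = split, deg_table = deg_table,
                        degs = degs, importances = imps, weight_table = wt,
                        selected_genes = selected, auc_table = auc_tab,
                        group_tests = gtests, immune_cor = icor,
                        enrichment = enr, truth = truth, summary = summary),
                   class = "PipelineResult")
  if (!is.null(config$out_dir)) write_pipeline_artifacts(res, config$out_dir)
  res
}

# write every stage artifact as TSV/JSON under out_dir
write_pipeline_artifacts <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  f <- function(...) file.path(out_dir, ...)
  write_expression(res$es, f("expression.tsv"), f("metadata.tsv"))
  write_split(res$split, f("split.json"))
  utils::write.table(attr(res$degs, "all"), f("deg_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(res$weight_table, f("weight_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (m in names(res$importances)) {
    v <- res$importances[[m]]
    utils::write.table(data.frame(gene = names(v$raw), raw_importance = v$raw),
                       f(paste0("importance_", m, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(res$auc_table))
    utils::write.table(res$auc_table, f("auc.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(res$immune_cor))
    utils::write.table(res$immune_cor, f("immune_correlation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$enrichment))
    utils::write.table(res$enrichment, f("enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  jsonlite::write_json(res$summary, f("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.PipelineResult <- function(x, ...) {
  cat("Biomarker-discovery pipeline result\n")
  cat(sprintf("  %d genes x %d samples; %d train / %d test\n",
              x$summary$n_genes, x$summary$n_samples, x$summary$n_train,
              x$summary$n_test))
  cat(sprintf("  DEGs passing filter: %d\n", x$summary$n_degs))
  cat(sprintf("  selected genes (overall weight > %s): %s\n",
              format(x$summary$weight_threshold),
              if (length(x$selected_genes))
                paste(x$selected_genes, collapse = ", ") else "<none>"))
  invisible(x)
}
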