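#' Classifier specification
#'
#' Hyperparameters for one of the six ensemble members. Defaults follow the
#' study design the pipeline emulates: lasso tuned over a 2000-value lambda
#' grid by 10-fold CV under binomial deviance/class loss; linear SVM with
#' cost tuned over 1..20; decision tree with complexity 1e-6; random forest
#' with 500 trees and OOB-tuned mtry; gradient boosting with 100 trees,
#' learning rate 0.01, subsample 0.8 and Bernoulli (logistic) loss; neural
#' network with a single hidden layer of 3 units and sum-of-squared-error
#' loss.
#'
#' @param algorithm One of `"lasso"`, `"svm_linear"`, `"decision_tree"`,
#'   `"random_forest"`, `"gbm"`, `"neural_net"`.
#' @param folds CV folds for tuned algorithms (default 10).
#' @param seed Integer seed used for CV folds, bootstraps, subsampling and
#'   weight initialization.
#' @param ... Algorithm-specific overrides: `nlambda` (lasso), `cost_grid`
#'   (svm), `cp` (tree), `n_trees` (forest/gbm), `learn_rate`, `sample_rate`,
#'   `max_depth` (gbm), `hidden` (neural net), `maxit`, `decay` (neural net).
#' @return A list of class `ModelSpec`.
#' @export
model_spec <- function(algorithm, folds = 10, seed = 234, ...) {
  algorithm <- match.arg(algorithm, c("lasso", "svm_linear", "decision_tree",
                                      "random_forest", "gbm", "neural_net"))
  if (folds < 2) stop("`folds` must be >= 2")
  defaults <- switch(algorithm,
    lasso = list(nlambda = 2000),
    svm_linear = list(cost_grid = 1:20),
    decision_tree = list(cp = 1e-6),
    random_forest = list(n_trees = 500),
    gbm = list(n_trees = 100, learn_rate = 0.01, sample_rate = 0.8,
               max_depth = 5),
    neural_net = list(hidden = 3, maxit = 500, decay = 1e-4))
  dots <- list(...)
  bad <- setdiff(names(dots), names(defaults))
  if (length(bad)) stop("unknown hyperparameters for ", algorithm, ": ",
                        paste(bad, collapse = ", "))
  defaults[names(dots)] <- dots
  structure(c(list(algorithm = algorithm, folds = folds,
                   seed = as.integer(seed)), defaults),
            class = "ModelSpec")
}

#' Misclassification error rate
#'
#' @param predictions,truth Equal-length label vectors.
#' @return Fraction of mismatches, in `[0, 1]`.
#' @export
error_rate <- function(predictions, truth) {
  if (length(predictions) != length(truth))
    stop("`predictions` and `truth` must have equal length")
  if (length(truth) == 0) stop("empty label vectors")
  mean(as.character(predictions) != as.character(truth))
}

# design matrices (samples x features) and 0/1 labels for a fitted split
ensemble_design <- function(es, split, features) {
  missing <- setdiff(features, rownames(es$exprs))
  if (length(missing)) stop("unknown features: ", paste(missing, collapse = ", "))
  tr <- subset_samples(es, split$train_ids)
  te <- subset_samples(es, split$test_ids)
  list(x_train = t(tr$exprs[features, , drop = FALSE]),
       x_test = t(te$exprs[features, , drop = FALSE]),
       y_train = factor(ifelse(is_case(tr), "case", "control"),
                        levels = c("control", "case")),
       y_test = factor(ifelse(is_case(te), "case", "control"),
                       levels = c("control", "case")))
}

# z-score columns by train statistics; zero-variance columns left centered
standardize_train <- function(x_train, x_test) {
  mu <- colMeans(x_train)
  sd <- apply(x_train, 2, stats::sd)
  sd[sd == 0] <- 1
  list(train = sweep(sweep(x_train, 2, mu), 2, sd, "/"),
       test = sweep(sweep(x_test, 2, mu), 2, sd, "/"))
}

# stratified CV fold ids so no fold is single-class
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (lev in levels(y)) {
    idx <- which(y == lev)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Fit one ensemble member and extract importances
#'
#' Tunes and fits one classifier on the training samples restricted to
#' `features`, extracts a nonnegative per-gene raw importance, and computes
#' misclassification error on the train and test samples (0.5 probability
#' cutoff for probabilistic models). Importance conventions: lasso — |coef|
#' on standardized features at the CV-selected lambda; linear SVM —
#' |hyperplane coefficient|; decision tree — summed Gini impurity decrease
#' over primary splits (surrogates excluded); random forest — mean decrease
#' in Gini impurity; gradient boosting — relative influence (normalized
#' split-gain); neural net — |Olden connection-weight product|. Features are
#' z-scored with training statistics for lasso, SVM and the neural net; the
#' tree-based models take raw values.
#'
#' @param es An [expr_set()].
#' @param split A [split_samples()] result.
#' @param features Gene ids to use as predictors (typically the DEGs).
#' @param spec A [model_spec()].
#' @return A list of class `ImportanceVector`: `model`, `raw` (named
#'   nonnegative numeric over all `features`), `train_error`, `test_error`,
#'   `details` (chosen hyperparameters).
#' @export
fit_model <- function(es, split, features, spec) {
  d <- ensemble_design(es, split, features)
  if (nlevels(droplevels(d$y_train)) < 2)
    stop("training labels contain a single class")
  set.seed(spec$seed + match(spec$algorithm,
                             c("lasso", "svm_linear", "decision_tree",
                               "random_forest", "gbm", "neural_net")))
  fitter <- switch(spec$algorithm,
                   lasso = fit_lasso, svm_linear = fit_svm,
                   decision_tree = fit_tree, random_forest = fit_forest,
                   gbm = fit_gbm, neural_net = fit_nnet)
  res <- fitter(d, spec)
  raw <- res$raw[features]
  raw[is.na(raw)] <- 0
  names(raw) <- features
  raw <- abs(raw)
  structure(list(model = spec$algorithm, raw = raw,
                 train_error = error_rate(res$pred_train, d$y_train),
                 test_error = error_rate(res$pred_test, d$y_test),
                 details = res$details),
            class = "ImportanceVector")
}

fit_lasso <- function(d, spec) {
  s <- standardize_train(d$x_train, d$x_test)
  foldid <- stratified_folds(d$y_train, spec$folds)
  cv <- glmnet::cv.glmnet(s$train, d$y_train, family = "binomial",
                          type.measure = "class", nlambda = spec$nlambda,
                          foldid = foldid, standardize = FALSE)
  beta <- as.numeric(stats::coef(cv, s = "lambda.min"))[-1]
  pr_tr <- stats::predict(cv, s$train, s = "lambda.min", type = "response")
  pr_te <- stats::predict(cv, s$test, s = "lambda.min", type = "response")
  lab <- function(p) factor(ifelse(p > 0.5, "case", "control"),
                            levels = c("control", "case"))
  list(raw = stats::setNames(abs(beta), colnames(s$train)),
       pred_train = lab(pr_tr), pred_test = lab(pr_te),
       details = list(lambda_min = cv$lambda.min, nlambda = spec$nlambda))
}

fit_svm <- function(d, spec) {
  s <- standardize_train(d$x_train, d$x_test)
  tn <- e1071::tune(e1071::svm, train.x = s$train, train.y = d$y_train,
                    kernel = "linear", scale = FALSE,
                    ranges = list(cost = spec$cost_grid),
                    tunecontrol = e1071::tune.control(cross = spec$folds))
  fit <- e1071::svm(s$train, d$y_train, kernel = "linear", scale = FALSE,
                    cost = tn$best.parameters$cost)
  w <- as.numeric(t(fit$coefs) %*% fit$SV)
  list(raw = stats::setNames(abs(w), colnames(s$train)),
       pred_train = stats::predict(fit, s$train),
       pred_test = stats::predict(fit, s$test),
       details = list(cost = tn$best.parameters$cost,
                      n_support_vectors = nrow(fit$SV)))
}

# sum of Gini improvements over primary splits, per variable
rpart_primary_importance <- function(fit) {
  frame <- fit$frame
  splits <- fit$splits
  imp <- numeric(0)
  if (is.null(splits) || nrow(frame) == 0) return(imp)
  idx <- 1
  for (i in seq_len(nrow(frame))) {
    if (frame$var[i] == "<leaf>") next
    v <- as.character(frame$var[i])
    imp[v] <- sum(imp[v], splits[idx, "improve"], na.rm = TRUE)
    idx <- idx + 1 + frame$ncompete[i] + frame$nsurrogate[i]
  }
  imp
}

fit_tree <- function(d, spec) {
  df_tr <- data.frame(d$x_train, check.names = FALSE)
  df_tr$.y <- d$y_train
  fit <- rpart::rpart(.y ~ ., data = df_tr, method = "class",
                      control = rpart::rpart.control(cp = spec$cp,
                                                     xval = spec$folds))
  list(raw = rpart_primary_importance(fit),
       pred_train = stats::predict(fit, data.frame(d$x_train, check.names = FALSE),
                                   type = "class"),
       pred_test = stats::predict(fit, data.frame(d$x_test, check.names = FALSE),
                                  type = "class"),
       details = list(cp = spec$cp, n_splits = sum(fit$frame$var != "<leaf>")))
}

fit_forest <- function(d, spec) {
  p <- ncol(d$x_train)
  grid <- sort(unique(pmax(1, pmin(p, floor(sqrt(p) * c(0.5, 1, 2))))))
  oob <- vapply(grid, function(m) {
    f <- randomForest::randomForest(d$x_train, d$y_train, ntree = spec$n_trees,
                                    mtry = m)
    f$err.rate[spec$n_trees, "OOB"]
  }, numeric(1))
  mtry <- grid[which.min(oob)]
  fit <- randomForest::randomForest(d$x_train, d$y_train,
                                    ntree = spec$n_trees, mtry = mtry,
                                    importance = FALSE)
  imp <- randomForest::importance(fit, type = 2)[, 1]
  list(raw = imp,
       pred_train = stats::predict(fit, d$x_train),
       pred_test = stats::predict(fit, d$x_test),
       details = list(mtry = mtry, n_trees = spec$n_trees,
                      oob_error = unname(min(oob))))
}

fit_gbm <- function(d, spec) {
  y01 <- as.numeric(d$y_train == "case")
  dtrain <- xgboost::xgb.DMatrix(d$x_train, label = y01)
  fit <- xgboost::xgb.train(params = list(objective = "binary:logistic",
                                          eta = spec$learn_rate,
                                          subsample = spec$sample_rate,
                                          max_depth = spec$max_depth,
                                          nthread = 1),
                            data = dtrain, nrounds = spec$n_trees,
                            verbose = 0)
  it <- xgboost::xgb.importance(model = fit)
  raw <- stats::setNames(rep(0, ncol(d$x_train)), colnames(d$x_train))
  if (!is.null(it) && nrow(it) > 0) raw[it$Feature] <- it$Gain
  lab <- function(p) factor(ifelse(p > 0.5, "case", "control"),
                            levels = c("control", "case"))
  list(raw = raw,
       pred_train = lab(stats::predict(fit, d$x_train)),
       pred_test = lab(stats::predict(fit, d$x_test)),
       details = list(n_trees = spec$n_trees, learn_rate = spec$learn_rate,
                      sample_rate = spec$sample_rate,
                      max_depth = spec$max_depth))
}

# Olden connection-weight importance for a single-hidden-layer nnet
olden_importance <- function(fit, feature_names) {
  p <- fit$n[1]; h <- fit$n[2]
  w_ih <- matrix(fit$wts[seq_len((p + 1) * h)], p + 1, h)[-1, , drop = FALSE]
  w_ho <- fit$wts[(p + 1) * h + 1 + seq_len(h)]
  stats::setNames(abs(as.numeric(w_ih %*% w_ho)), feature_names)
}

fit_nnet <- function(d, spec) {
  s <- standardize_train(d$x_train, d$x_test)
  y01 <- as.numeric(d$y_train == "case")
  fit <- nnet::nnet(s$train, y01, size = spec$hidden, decay = spec$decay,
                    maxit = spec$maxit, entropy = FALSE, trace = FALSE)
  lab <- function(p) factor(ifelse(p > 0.5, "case", "control"),
                            levels = c("control", "case"))
  list(raw = olden_importance(fit, colnames(s$train)),
       pred_train = lab(stats::predict(fit, s$train)),
       pred_test = lab(stats::predict(fit, s$test)),
       details = list(hidden = spec$hidden, decay = spec$decay,
                      maxit = spec$maxit))
}

#' Fit all six ensemble members
#'
#' @inheritParams fit_model
#' @param seed Pipeline seed shared by all members.
#' @param specs Optional named list of [model_spec()] overrides.
#' @return Named list of `ImportanceVector`s in the canonical model order
#'   `lasso, svm_linear, random_forest, neural_net, gbm, decision_tree`.
#' @export
fit_all_models <- function(es, split, features, seed = 234, specs = NULL) {
  algos <- c("lasso", "svm_linear", "random_forest", "neural_net", "gbm",
             "decision_tree")
  out <- lapply(algos, function(a) {
    sp <- if (!is.null(specs) && !is.null(specs[[a]])) specs[[a]]
          else model_spec(a, seed = seed)
    fit_model(es, split, features, sp)
  })
  stats::setNames(out, algos)
}
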