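# Classification harness: five models evaluated on the selected features,
# before vs after harmonization, with stratified splits, 5-fold CV, 95%
# confidence intervals, ROC curves and feature-importance rankings.

model_defaults <- list(
  lasso = list(penalty = 0.1, max_iter = 1000L),
  logistic = list(penalty_type = "l2", C = 1),
  random_forest = list(n_trees = 100L, max_depth = 8L),
  svm = list(cost = 2, kernel = "radial", gamma = "scale"),
  neural_net = list(activation = "relu", optimizer = "sgd",
                    learning_rate = 0.01, max_iter = 200L,
                    hidden_layers = 5L, hidden_units = 32L)
)

#' Specify one of the five classification models
#'
#' Hyperparameter defaults follow the study configuration: lasso (penalty
#' 0.1, 1000 iterations, used as a classifier by thresholding its continuous
#' prediction at 0.5), L2-penalized logistic regression, random forest (100
#' trees, maximum depth 8), RBF-kernel SVM (cost 2, kernel coefficient
#' "scale" = 1 / (n_features * var(train))), and a 5-hidden-layer ReLU
#' network trained by SGD (learning rate 0.01, 200 epochs; 32 units per
#' hidden layer).
#'
#' @param name one of `"lasso"`, `"logistic"`, `"random_forest"`, `"svm"`,
#'   `"neural_net"`.
#' @param hyperparameters optional named list overriding the defaults; every
#'   key of the default set must be present after merging.
#' @param seed integer seed controlling any model randomness.
#' @return a list of class `"model_spec"`.
#' @export
model_spec <- function(name, hyperparameters = NULL, seed = 1L) {
  name <- match.arg(name, names(model_defaults))
  hp <- utils::modifyList(model_defaults[[name]],
                          as.list(hyperparameters %||% list()))
  missing_keys <- setdiff(names(model_defaults[[name]]), names(hp))
  if (length(missing_keys)) {
    stop("configuration error: missing hyperparameter(s) for ", name, ": ",
         paste(missing_keys, collapse = ", "))
  }
  structure(list(name = name, hyperparameters = hp, seed = as.integer(seed)),
            class = "model_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The five study model specifications
#' @param seed shared integer seed.
#' @return named list of [model_spec()]s.
#' @export
default_model_specs <- function(seed = 1L) {
  stats::setNames(lapply(names(model_defaults), model_spec, seed = seed),
                  names(model_defaults))
}

#' Stratified train/test split
#'
#' Splits samples into train and test sets at the given ratio, stratified by
#' class: each class contributes `round(ratio * n_class)` training samples.
#'
#' @param table a [feature_table()] (>= 5 samples per class).
#' @param ratio training fraction, default 0.8.
#' @param seed integer seed.
#' @return a list of class `"split_plan"` with `train_indices`,
#'   `test_indices`, `ratio`, `stratified`, `seed`.
#' @export
make_split <- function(table, ratio = 0.8, seed = 1L) {
  stopifnot(is_feature_table(table), ratio > 0, ratio < 1)
  cls <- table$class
  if (any(table(cls) < 5)) stop("split error: need >= 5 samples per class")
  train <- integer(0)
  withr::with_seed(seed, {
    for (c0 in sort(unique(cls))) {
      idx <- which(cls == c0)
      n_train <- round(ratio * length(idx))
      train <- c(train, sample(idx, n_train))
    }
  })
  train <- sort(train)
  test <- setdiff(seq_len(nrow(table)), train)
  if (length(unique(cls[train])) < 2 || length(unique(cls[test])) < 2) {
    stop("split error: a class is absent from the train or test side")
  }
  structure(list(train_indices = train, test_indices = test,
                 ratio = ratio, stratified = TRUE, seed = as.integer(seed)),
            class = "split_plan")
}

# Standardize with training-fold statistics only (no test-fold leakage).
standardize_train_test <- function(x_train, x_test) {
  mu <- colMeans(x_train)
  sdev <- apply(x_train, 2, stats::sd)
  sdev[sdev == 0] <- 1
  list(train = sweep(sweep(x_train, 2, mu), 2, sdev, "/"),
       test = sweep(sweep(x_test, 2, mu), 2, sdev, "/"))
}

fit_model <- function(spec, x, y) {
  hp <- spec$hyperparameters
  switch(spec$name,
    lasso = glmnet::glmnet(x, y, family = "gaussian", alpha = 1,
                           lambda = hp$penalty, standardize = FALSE,
                           maxit = hp$max_iter),
    logistic = glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                              lambda = 1 / (hp$C * nrow(x)),
                              standardize = FALSE),
    random_forest = ranger::ranger(
      x = as.data.frame(x), y = factor(y, levels = c(0, 1)),
      num.trees = hp$n_trees, max.depth = hp$max_depth,
      probability = TRUE, importance = "impurity", seed = spec$seed),
    svm = {
      gam <- if (identical(hp$gamma, "scale")) {
        1 / (ncol(x) * stats::var(as.vector(x)))
      } else hp$gamma
      e1071::svm(x, factor(y, levels = c(0, 1)), type = "C-classification",
                 kernel = hp$kernel, cost = hp$cost, gamma = gam,
                 scale = FALSE)
    },
    neural_net = mlp_fit(x, y, hidden = rep(hp$hidden_units, hp$hidden_layers),
                         learning_rate = hp$learning_rate,
                         epochs = hp$max_iter, seed = spec$seed))
}

# Continuous score for AUC (probability where available, decision value for
# the SVM, raw regression prediction for the lasso classifier).
predict_score <- function(spec, fit, x) {
  switch(spec$name,
    lasso = as.numeric(stats::predict(fit, x)),
    logistic = as.numeric(stats::predict(fit, x, type = "response")),
    random_forest = stats::predict(fit, as.data.frame(x))$predictions[, "1"],
    svm = as.numeric(attr(stats::predict(fit, x, decision.values = TRUE),
                          "decision.values")) *
      (if (fit$labels[1] == 2) 1 else -1),  # orient: larger = class "1"
    neural_net = mlp_predict(fit, x))
}

score_threshold <- function(spec) if (spec$name == "svm") 0 else 0.5

# Confusion-matrix metrics (positive class = 1) plus trapezoidal AUC.
classification_metrics <- function(y, score, threshold = 0.5) {
  pred <- as.integer(score > threshold)
  tp <- sum(pred == 1 & y == 1)
  fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  tn <- sum(pred == 0 & y == 0)
  acc <- (tp + tn) / length(y)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  roc <- pROC::roc(response = y, predictor = score, levels = c(0, 1),
                   direction = "<", quiet = TRUE)
  c(accuracy = acc, precision = prec, recall = rec,
    auc = as.numeric(pROC::auc(roc)))
}

roc_curve_points <- function(y, score) {
  roc <- pROC::roc(response = y, predictor = score, levels = c(0, 1),
                   direction = "<", quiet = TRUE)
  ord <- order(1 - roc$specificities, roc$sensitivities)
  list(fpr = (1 - roc$specificities)[ord], tpr = roc$sensitivities[ord])
}

importance_ranking <- function(spec, fit, feature_names_) {
  imp <- switch(spec$name,
    logistic = {
      v <- abs(as.numeric(fit$beta))
      stats::setNames(v, rownames(fit$beta))
    },
    random_forest = ranger::importance(fit),
    NULL)
  if (is.null(imp)) return(NULL)
  imp <- imp[order(-imp, names(imp))]
  data.frame(feature_name = names(imp), score = as.numeric(imp),
             rank = seq_along(imp), stringsAsFactors = FALSE)
}

#' Train a model on a training set and evaluate it on a test set
#'
#' Features are standardized with training-set statistics only. Returns the
#' classification metrics, ROC curve points, continuous scores and the fitted
#' model handle (with the feature-importance ranking for the logistic and
#' random-forest models).
#'
#' @param spec a [model_spec()].
#' @param train,test `feature_table`s with identical feature sets.
#' @return list with `metrics` (accuracy, precision, recall, auc),
#'   `roc_curve`, `scores`, `fit`, `importance`.
#' @export
train_eval <- function(spec, train, test) {
  stopifnot(inherits(spec, "model_spec"),
            is_feature_table(train), is_feature_table(test),
            identical(feature_names(train), feature_names(test)))
  y_train <- train$class
  if (length(unique(y_train)) < 2) {
    stop("evaluation error: training fold contains a single class")
  }
  std <- standardize_train_test(feature_matrix(train), feature_matrix(test))
  fit <- fit_model(spec, std$train, y_train)
  score <- predict_score(spec, fit, std$test)
  y_test <- test$class
  list(metrics = classification_metrics(y_test, score, score_threshold(spec)),
       roc_curve = roc_curve_points(y_test, score),
       scores = score,
       fit = fit,
       importance = importance_ranking(spec, fit, feature_names(train)))
}

# Stratified k-fold assignment: within each class, shuffled samples are dealt
# round-robin to folds.
stratified_folds <- function(cls, k, seed) {
  fold <- integer(length(cls))
  withr::with_seed(seed, {
    for (c0 in sort(unique(cls))) {
      idx <- sample(which(cls == c0))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Stratified k-fold cross-validation of one model
#'
#' Per-fold accuracy, precision, recall and AUC, with 95% confidence
#' intervals by the normal approximation `mean +/- 1.96 sd / sqrt(k)`
#' (clipped to `[0, 1]`).
#'
#' @param spec a [model_spec()].
#' @param table a `feature_table` (typically restricted to the selected
#'   features).
#' @param k number of folds (default 5); must not exceed the minority-class
#'   count.
#' @param seed integer seed for the fold assignment.
#' @return list with `folds` (k x metric data.frame), `summary`
#'   (mean / ci_lo / ci_hi per metric), `fold_assignment`.
#' @export
cross_validate <- function(spec, table, k = 5L, seed = 1L) {
  stopifnot(is_feature_table(table))
  if (k > nrow(table)) stop("input error: k exceeds the sample count")
  if (k > min(table(table$class))) {
    stop("input error: k exceeds the minority-class count")
  }
  fold <- stratified_folds(table$class, k, seed)
  per_fold <- matrix(NA_real_, k, 4,
                     dimnames = list(NULL, c("accuracy", "precision",
                                             "recall", "auc")))
  for (f in seq_len(k)) {
    tr <- table[fold != f, , drop = FALSE]
    te <- table[fold == f, , drop = FALSE]
    class(tr) <- class(te) <- c("feature_table", "data.frame")
    per_fold[f, ] <- train_eval(spec, tr, te)$metrics
  }
  mu <- colMeans(per_fold)
  se <- apply(per_fold, 2, stats::sd) / sqrt(k)
  summary <- data.frame(metric = colnames(per_fold),
                        mean = unname(mu),
                        ci_lo = pmax(unname(mu - 1.96 * se), 0),
                        ci_hi = pmin(unname(mu + 1.96 * se), 1),
                        stringsAsFactors = FALSE)
  list(folds = as.data.frame(per_fold), summary = summary,
       fold_assignment = fold)
}

#' Evaluate the model suite on one arm (a feature table)
#'
#' Runs stratified 5-fold cross-validation for every model and additionally
#' fits each model on a stratified 8:2 train/test split for the ROC curve and
#' the feature-importance rankings.
#'
#' @param table a `feature_table` restricted to the evaluation features.
#' @param specs named list of [model_spec()]s (default: all five).
#' @param k CV folds.
#' @param ratio train fraction of the holdout split.
#' @param seed integer seed shared by the fold assignment and the split.
#' @return list of class `"eval_report"`: per model `cv`, `holdout`
#'   (metrics, roc_curve, importance).
#' @export
evaluate_models <- function(table, specs = default_model_specs(), k = 5L,
                            ratio = 0.8, seed = 1L) {
  split <- make_split(table, ratio = ratio, seed = seed)
  train <- table[split$train_indices, , drop = FALSE]
  test <- table[split$test_indices, , drop = FALSE]
  class(train) <- class(test) <- c("feature_table", "data.frame")
  out <- lapply(specs, function(sp) {
    cv <- cross_validate(sp, table, k = k, seed = seed)
    ho <- train_eval(sp, train, test)
    list(cv = cv,
         holdout = list(metrics = ho$metrics, roc_curve = ho$roc_curve,
                        importance = ho$importance))
  })
  structure(c(out, list(.split = split)), class = "eval_report")
}

#' Compare the without- vs with-harmonization arms
#'
#' Paired metric deltas (`with - without`) per model from the
#' cross-validation means, plus — for models exposing importances — the
#' Spearman correlation of the two importance rankings and the per-feature
#' signed rank shift.
#'
#' @param report_without,report_with `eval_report`s from [evaluate_models()]
#'   computed with the same models, feature set and seed.
#' @return list with `deltas` (model x metric data.frame) and
#'   `importance_change` (per model: `spearman`, `rank_change` table).
#' @export
compare_arms <- function(report_without, report_with) {
  models_wo <- setdiff(names(report_without), ".split")
  models_wi <- setdiff(names(report_with), ".split")
  if (!identical(models_wo, models_wi)) {
    stop("comparison error: the two arms evaluate different model lists")
  }
  deltas <- do.call(rbind, lapply(models_wo, function(m) {
    s0 <- report_without[[m]]$cv$summary
    s1 <- report_with[[m]]$cv$summary
    data.frame(model = m, metric = s0$metric,
               without = s0$mean, with = s1$mean,
               delta = s1$mean - s0$mean, stringsAsFactors = FALSE)
  }))
  importance_change <- list()
  for (m in models_wo) {
    i0 <- report_without[[m]]$holdout$importance
    i1 <- report_with[[m]]$holdout$importance
    if (is.null(i0) || is.null(i1)) next
    shared <- intersect(i0$feature_name, i1$feature_name)
    r0 <- i0$rank[match(shared, i0$feature_name)]
    r1 <- i1$rank[match(shared, i1$feature_name)]
    importance_change[[m]] <- list(
      spearman = stats::cor(r0, r1, method = "spearman"),
      rank_change = data.frame(feature_name = shared,
                               rank_without = r0, rank_with = r1,
                               shift = r0 - r1, stringsAsFactors = FALSE))
  }
  list(deltas = deltas, importance_change = importance_change)
}
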