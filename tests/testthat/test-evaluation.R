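make_separable_table <- function(n_per_class = 30, G = 5, gap = 6, seed = 2) {
  withr::with_seed(seed, {
    cls <- rep(c(0L, 1L), each = n_per_class)
    values <- matrix(rnorm(2 * n_per_class * G), ncol = G) + gap * cls
    colnames(values) <- sprintf("f%d", seq_len(G))
  })
  feature_table(values, batch = rep(c("a", "b"), n_per_class), class = cls)
}

test_that("model specs carry the study hyperparameters and reject gaps", {
  specs <- default_model_specs()
  expect_named(specs, c("lasso", "logistic", "random_forest", "svm",
                        "neural_net"))
  expect_equal(specs$lasso$hyperparameters$penalty, 0.1)
  expect_equal(specs$lasso$hyperparameters$max_iter, 1000L)
  expect_equal(specs$random_forest$hyperparameters$n_trees, 100L)
  expect_equal(specs$random_forest$hyperparameters$max_depth, 8L)
  expect_equal(specs$svm$hyperparameters$cost, 2)
  expect_identical(specs$svm$hyperparameters$gamma, "scale")
  expect_equal(specs$neural_net$hyperparameters$hidden_layers, 5L)
  expect_error(model_spec("catboost"))
})

test_that("stratified splitting reproduces the study arithmetic", {
  big <- make_separable_table(n_per_class = 135, G = 3)
  sp <- make_split(big, ratio = 0.8, seed = 1)
  cls_train <- big$class[sp$train_indices]
  expect_equal(sum(cls_train == 0), 108)
  expect_equal(sum(cls_train == 1), 108)
  expect_equal(length(sp$test_indices), 54)
  expect_setequal(c(sp$train_indices, sp$test_indices), seq_len(270))
  expect_length(intersect(sp$train_indices, sp$test_indices), 0)
  # small case: 10 samples at 0.8 -> 8 train, 2 test
  small <- make_separable_table(n_per_class = 5, G = 3)
  sp2 <- make_split(small, ratio = 0.8, seed = 1)
  expect_length(sp2$train_indices, 8)
  expect_length(sp2$test_indices, 2)
  # determinism
  expect_identical(make_split(big, seed = 9)$train_indices,
                   make_split(big, seed = 9)$train_indices)
  expect_error(make_split(make_separable_table(n_per_class = 3), seed = 1),
               "split error")
})

test_that("metrics agree with a hand-computed confusion matrix", {
  # 4 predictions: y = 1,1,0,0; scores 0.9, 0.2, 0.8, 0.1
  # at 0.5: TP=1 FN=1 FP=1 TN=1 -> acc 0.5, precision 0.5, recall 0.5
  # ranked pairs: concordant (0.9>0.8),(0.9>0.1),(0.2>0.1); discordant (0.2<0.8)
  # AUC = 3/4
  m <- radcombat:::classification_metrics(c(1, 1, 0, 0),
                                          c(0.9, 0.2, 0.8, 0.1))
  expect_equal(unname(m["accuracy"]), 0.5)
  expect_equal(unname(m["precision"]), 0.5)
  expect_equal(unname(m["recall"]), 0.5)
  expect_equal(unname(m["auc"]), 0.75)
})

test_that("every model solves a well-separated problem perfectly", {
  tab <- make_separable_table()
  sp <- make_split(tab, seed = 4)
  train <- tab[sp$train_indices, ]; test <- tab[sp$test_indices, ]
  class(train) <- class(test) <- c("feature_table", "data.frame")
  for (spec in default_model_specs(seed = 4)) {
    res <- train_eval(spec, train, test)
    expect_equal(unname(res$metrics["auc"]), 1, tolerance = 1e-9,
                 label = spec$name)
    expect_equal(unname(res$metrics["accuracy"]), 1, tolerance = 1e-9)
    # ROC contract: starts at (0,0), ends at (1,1), nondecreasing
    expect_equal(res$roc_curve$fpr[1], 0)
    expect_equal(utils::tail(res$roc_curve$tpr, 1), 1)
    expect_true(all(diff(res$roc_curve$tpr) >= 0))
  }
})

test_that("permuted labels give chance-level AUC", {
  tab <- make_separable_table(n_per_class = 40, gap = 6)
  spec <- model_spec("random_forest", seed = 1)
  aucs <- vapply(1:20, function(s) {
    perm <- tab
    withr::with_seed(1000 + s, perm$class <- sample(perm$class))
    class(perm) <- c("feature_table", "data.frame")
    sp <- make_split(perm, seed = s)
    tr <- perm[sp$train_indices, ]; te <- perm[sp$test_indices, ]
    class(tr) <- class(te) <- c("feature_table", "data.frame")
    unname(train_eval(spec, tr, te)$metrics["auc"])
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("the random forest uses the configured forest size and depth", {
  tab <- make_separable_table()
  sp <- make_split(tab, seed = 3)
  tr <- tab[sp$train_indices, ]; te <- tab[sp$test_indices, ]
  class(tr) <- class(te) <- c("feature_table", "data.frame")
  res <- train_eval(model_spec("random_forest", seed = 3), tr, te)
  expect_equal(res$fit$num.trees, 100)
  depths <- suppressWarnings(vapply(seq_len(100), function(t) {
    max(ranger::treeInfo(res$fit, t)$depth, na.rm = TRUE)
  }, numeric(1)))
  expect_lte(max(depths), 8)
})

test_that("cross-validation folds partition the data and CIs are clipped", {
  tab <- make_separable_table(n_per_class = 25)
  cv <- cross_validate(model_spec("logistic"), tab, k = 5, seed = 7)
  expect_equal(sort(unique(cv$fold_assignment)), 1:5)
  expect_length(cv$fold_assignment, nrow(tab))
  # stratification: every fold holds ~n/k samples of each class
  per_fold <- table(cv$fold_assignment, tab$class)
  expect_true(all(per_fold == 5))
  expect_true(all(cv$summary$ci_lo >= 0 & cv$summary$ci_hi <= 1))
  expect_true(all(cv$summary$mean >= cv$summary$ci_lo - 1e-12))
  expect_error(cross_validate(model_spec("logistic"), tab, k = 26),
               "minority-class")
})

test_that("standardization uses training statistics only (no leakage)", {
  tab <- make_separable_table(n_per_class = 30)
  sp <- make_split(tab, seed = 5)
  tr <- tab[sp$train_indices, ]; te <- tab[sp$test_indices, ]
  corrupted <- te
  corrupted$class <- 1L - corrupted$class   # flip every held-out label
  class(tr) <- class(te) <- class(corrupted) <- c("feature_table",
                                                  "data.frame")
  spec <- model_spec("logistic", seed = 5)
  r1 <- train_eval(spec, tr, te)
  r2 <- train_eval(spec, tr, corrupted)
  expect_identical(as.numeric(r1$fit$beta), as.numeric(r2$fit$beta))
  expect_identical(r1$scores, r2$scores)
})

test_that("arm comparison is zero on identical arms and antisymmetric", {
  tab <- make_separable_table(n_per_class = 20, gap = 2)
  specs <- default_model_specs(seed = 2)[c("logistic", "random_forest")]
  rep1 <- evaluate_models(tab, specs, seed = 2)
  rep2 <- evaluate_models(tab, specs, seed = 2)
  cmp <- compare_arms(rep1, rep2)
  expect_true(all(cmp$deltas$delta == 0))
  for (ic in cmp$importance_change) expect_equal(ic$spearman, 1)
  # antisymmetry on genuinely different arms
  shifted <- tab
  shifted[, feature_names(tab)] <- feature_matrix(tab) +
    matrix(rnorm(nrow(tab) * 5, sd = 3), ncol = 5)
  class(shifted) <- c("feature_table", "data.frame")
  rep3 <- evaluate_models(shifted, specs, seed = 2)
  d13 <- compare_arms(rep1, rep3)$deltas$delta
  d31 <- compare_arms(rep3, rep1)$deltas$delta
  expect_equal(d13, -d31)
  expect_error(compare_arms(rep1, rep1[c("logistic", ".split")]),
               "comparison error")
})
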