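#' Screen features by L1-penalized (lasso) regression
#'
#' Fits an L1-penalized linear regression of the binary class label on the
#' internally standardized features at a fixed penalty, ranks features by
#' absolute coefficient (ties broken by feature name for reproducibility) and
#' returns the top `n_keep` features with nonzero coefficients.
#'
#' The selection is intended to be computed once, on the unharmonized data,
#' so that before/after-harmonization comparisons hold the feature set fixed.
#'
#' @param table a [feature_table()] with binary class labels.
#' @param penalty lasso penalty (the `1/(2n) RSS + penalty * |coef|_1`
#'   parameterization); study default 0.1.
#' @param n_keep number of features to retain (study default 20).
#' @param max_iter maximum coordinate-descent iterations (study default 1000).
#' @return a list of class `"selection_result"` with `selected_names`
#'   (ranked), `coefficients` (on the standardized scale), `penalty`,
#'   `n_requested`.
#' @export
lasso_select <- function(table, penalty = 0.1, n_keep = 20L,
                         max_iter = 1000L) {
  stopifnot(is_feature_table(table), penalty > 0, n_keep >= 1)
  x <- feature_matrix(table)
  y <- table$class
  # standardize internally (population sd, as the penalized fit assumes)
  mu <- colMeans(x)
  sdev <- sqrt(colMeans(sweep(x, 2, mu)^2))
  keepable <- sdev > 0
  xs <- sweep(sweep(x[, keepable, drop = FALSE], 2, mu[keepable]), 2,
              sdev[keepable], "/")
  fit <- glmnet::glmnet(xs, y, family = "gaussian", alpha = 1,
                        lambda = penalty, standardize = FALSE,
                        maxit = max_iter)
  coefs <- as.numeric(fit$beta)
  names(coefs) <- colnames(xs)
  nz <- coefs[coefs != 0]
  if (length(nz) == 0) {
    stop("selection error: all coefficients are zero at penalty ", penalty,
         "; try a smaller penalty")
  }
  ord <- order(-abs(nz), names(nz))
  nz <- nz[ord]
  sel <- utils::head(nz, n_keep)
  structure(list(selected_names = names(sel),
                 coefficients = sel,
                 penalty = penalty,
                 n_requested = as.integer(n_keep)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d/%d features at penalty %g\n",
              length(x$selected_names), x$n_requested, x$penalty))
  invisible(x)
}

#' Subset a feature table to a set of features
#' @param table a `feature_table`.
#' @param features feature names (or a `selection_result`).
#' @return a `feature_table` restricted to those features, original order of
#'   samples preserved.
#' @export
subset_features <- function(table, features) {
  if (inherits(features, "selection_result")) {
    features <- features$selected_names
  }
  missing_f <- setdiff(features, feature_names(table))
  if (length(missing_f)) {
    stop("unknown feature(s): ", paste(missing_f, collapse = ", "))
  }
  out <- table[, c("sample_id", "batch", "class", features), drop = FALSE]
  class(out) <- c("feature_table", "data.frame")
  out
}
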