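# Parametric empirical-Bayes ComBat harmonization.
#
# Model: y_ijg = alpha_g + X beta_g + gamma_ig + delta_ig * eps_ijg, with
# batch i, sample j, feature g, protected covariates X and
# eps ~ N(0, sigma_g^2). Location/scale estimates are obtained by least
# squares under the constraint that batch effects average (weighted by batch
# size) to zero; per-batch additive and multiplicative effects are then
# shrunk across features via a normal / inverse-gamma empirical prior and
# removed:
#   yhat_ijg = (y_ijg - alpha_g - X beta_g - gamma*_ig) / delta*_ig
#             + alpha_g + X beta_g.

# Build the covariate design (no intercept; the intercept lives in the batch
# indicators). Factors expand to treatment-coded dummies.
covariate_design <- function(table, covariates) {
  if (is.null(covariates) || length(covariates) == 0) {
    return(matrix(numeric(0), nrow(table), 0))
  }
  missing_cov <- setdiff(covariates, names(table))
  if (length(missing_cov)) {
    stop("unknown covariate column(s): ", paste(missing_cov, collapse = ", "))
  }
  df <- as.data.frame(table)[, covariates, drop = FALSE]
  mm <- stats::model.matrix(stats::reformulate(covariates), df)
  mm[, -1, drop = FALSE]
}

#' Fit the location/scale model and standardize the data
#'
#' Least-squares fit of per-feature grand mean, protected-covariate effects
#' and per-batch means, followed by standardization: `Z = (y - alpha_hat -
#' X beta_hat) / sigma_hat`. Per-batch means (`gamma_hat`) and variances
#' (`delta2_hat`) of `Z` are the raw batch-effect estimates that the
#' empirical-Bayes step later shrinks.
#'
#' @param table a [feature_table()] with >= 2 batches and >= 2 samples per
#'   batch.
#' @param covariates character vector of label columns to protect during
#'   harmonization; default `"class"` (the texture class must never be
#'   removed along with the scanner effect).
#' @return a list with `model` (a `combat_model` holding `alpha_hat`,
#'   `beta_hat`, `sigma2_hat`, `gamma_hat`, `delta2_hat`) and `Z` (the
#'   standardized sample-by-feature matrix).
#' @export
fit_standardize <- function(table, covariates = "class") {
  validate_for_harmonization(table)
  Y <- feature_matrix(table)
  n <- nrow(Y); G <- ncol(Y)
  batch <- droplevels(table$batch)
  levels_b <- levels(batch)
  nb <- length(levels_b)
  n_i <- as.integer(table(batch))

  B <- stats::model.matrix(~ 0 + batch)
  colnames(B) <- levels_b
  C <- covariate_design(table, covariates)
  X <- cbind(B, C)
  if (qr(X)$rank < ncol(X)) {
    stop("model error: covariate(s) confounded with batch ",
         "(design matrix is rank-deficient)")
  }
  coefs <- solve(crossprod(X), crossprod(X, Y))
  batch_means <- coefs[seq_len(nb), , drop = FALSE]
  beta_hat <- coefs[-seq_len(nb), , drop = FALSE]

  alpha_hat <- drop(crossprod(n_i / n, batch_means))
  fitted <- X %*% coefs
  sigma2_hat <- colSums((Y - fitted)^2) / n
  if (any(sigma2_hat <= 0)) {
    bad <- feature_names(table)[sigma2_hat <= 0]
    stop("zero-variance feature(s): ", paste(bad, collapse = ", "))
  }

  stand_mean <- matrix(alpha_hat, n, G, byrow = TRUE)
  if (ncol(C) > 0) stand_mean <- stand_mean + C %*% beta_hat
  Z <- (Y - stand_mean) / matrix(sqrt(sigma2_hat), n, G, byrow = TRUE)

  gamma_hat <- matrix(NA_real_, nb, G, dimnames = list(levels_b, colnames(Y)))
  delta2_hat <- gamma_hat
  for (i in seq_len(nb)) {
    Zi <- Z[batch == levels_b[i], , drop = FALSE]
    gamma_hat[i, ] <- colMeans(Zi)
    delta2_hat[i, ] <- apply(Zi, 2, stats::var)
  }
  floor_idx <- delta2_hat < 1e-8
  if (any(floor_idx)) {
    warning(sum(floor_idx), " within-batch zero-variance cell(s); ",
            "delta2_hat floored at 1e-8")
    delta2_hat[floor_idx] <- 1e-8
  }

  model <- structure(list(
    alpha_hat = stats::setNames(alpha_hat, colnames(Y)),
    beta_hat = beta_hat,
    sigma2_hat = stats::setNames(sigma2_hat, colnames(Y)),
    gamma_hat = gamma_hat,
    delta2_hat = delta2_hat,
    gamma_star = NULL, delta2_star = NULL,
    hyper_gamma_mean = NULL, hyper_gamma_var = NULL,
    hyper_delta_lambda = NULL, hyper_delta_theta = NULL,
    batch_levels = levels_b,
    design_columns = colnames(C),
    n_per_batch = stats::setNames(n_i, levels_b),
    converged = NA, n_iter = NA_integer_),
    class = "combat_model")
  list(model = model, Z = Z)
}

#' @export
print.combat_model <- function(x, ...) {
  cat(sprintf("<combat_model> %d batches (%s), %d features%s\n",
              length(x$batch_levels),
              paste(x$batch_levels, collapse = ", "),
              length(x$alpha_hat),
              if (!is.null(x$gamma_star)) {
                sprintf("; EB-adjusted (%s in %d iterations)",
                        if (isTRUE(x$converged)) "converged" else "NOT converged",
                        x$n_iter)
              } else "; EB step pending"))
  invisible(x)
}

#' Estimate the empirical-Bayes hyperpriors
#'
#' Method-of-moments hyperprior estimates over features within each batch:
#' a normal prior `gamma_ig ~ N(hyper_gamma_mean_i, hyper_gamma_var_i)` with
#' moments taken from `gamma_hat[i, ]`, and an inverse-gamma prior
#' `delta2_ig ~ InvGamma(lambda_i, theta_i)` with `(lambda, theta)` matched
#' to the mean and variance of `delta2_hat[i, ]`.
#'
#' @param model a `combat_model` from [fit_standardize()], >= 3 features.
#' @return the model with `hyper_*` fields filled.
#' @export
eb_hyperpriors <- function(model) {
  stopifnot(inherits(model, "combat_model"))
  G <- length(model$alpha_hat)
  if (G < 3) {
    stop("hyperprior error: at least 3 features needed for moment estimates")
  }
  nb <- length(model$batch_levels)
  gm <- gv <- la <- th <- stats::setNames(numeric(nb), model$batch_levels)
  for (i in seq_len(nb)) {
    g <- model$gamma_hat[i, ]
    d2 <- model$delta2_hat[i, ]
    gm[i] <- mean(g)
    gv[i] <- stats::var(g)
    m <- mean(d2); s2 <- stats::var(d2)
    if (s2 > 0) {
      la[i] <- (2 * s2 + m^2) / s2
      th[i] <- (m * s2 + m^3) / s2
    } else {
      # all delta2_hat equal: prior degenerate at m, no shrinkage needed
      la[i] <- Inf
      th[i] <- Inf
    }
  }
  model$hyper_gamma_mean <- gm
  model$hyper_gamma_var <- gv
  model$hyper_delta_lambda <- la
  model$hyper_delta_theta <- th
  model
}

#' Empirical-Bayes adjustment of the batch-effect estimates
#'
#' Iterates the conditional posterior updates until the largest absolute
#' parameter change drops below `tol`:
#' `gamma* = (n_i tau2 gamma_hat + delta2* gbar) / (n_i tau2 + delta2*)`
#' (precision-weighted combination of the per-feature estimate and the prior
#' mean), and `delta2* = (theta + 0.5 * sum_j (Z_jg - gamma*)^2) /
#' (n_i/2 + lambda - 1)` (inverse-gamma posterior mean). Degenerate
#' hyperpriors short-circuit: zero prior variance gives full shrinkage to the
#' prior mean, an infinite one leaves the estimates untouched.
#'
#' @param model a `combat_model` with hyperpriors (see [eb_hyperpriors()]).
#' @param Z the standardized matrix from [fit_standardize()].
#' @param batch per-sample batch labels aligned with `Z` rows.
#' @param tol convergence tolerance on the maximum absolute change.
#' @param max_iter iteration cap; non-convergence raises a warning and is
#'   recorded in the model, never silently ignored.
#' @return the model with `gamma_star`, `delta2_star`, `converged`, `n_iter`.
#' @export
eb_adjust <- function(model, Z, batch, tol = 1e-4, max_iter = 100L) {
  stopifnot(inherits(model, "combat_model"))
  if (is.null(model$hyper_gamma_mean)) {
    stop("hyperpriors missing: call eb_hyperpriors() first")
  }
  batch <- factor(batch, levels = model$batch_levels)
  nb <- length(model$batch_levels)
  gamma_star <- model$gamma_hat
  delta2_star <- model$delta2_hat
  conv <- TRUE; iters <- 0L
  for (i in seq_len(nb)) {
    Zi <- Z[batch == model$batch_levels[i], , drop = FALSE]
    n_i <- nrow(Zi)
    ghat <- model$gamma_hat[i, ]
    gbar <- model$hyper_gamma_mean[i]
    t2 <- model$hyper_gamma_var[i]
    lambda <- model$hyper_delta_lambda[i]
    theta <- model$hyper_delta_theta[i]
    g_old <- ghat
    d_old <- model$delta2_hat[i, ]
    it <- 0L
    repeat {
      it <- it + 1L
      g_new <- if (is.infinite(t2)) ghat
      else (n_i * t2 * ghat + d_old * gbar) / (n_i * t2 + d_old)
      d_new <- if (!is.finite(lambda) || !is.finite(theta)) {
        model$delta2_hat[i, ]
      } else {
        ss <- colSums(sweep(Zi, 2, g_new, "-")^2)
        (theta + 0.5 * ss) / (n_i / 2 + lambda - 1)
      }
      change <- max(abs(g_new - g_old), abs(d_new - d_old))
      g_old <- g_new; d_old <- d_new
      if (change < tol || it >= max_iter) break
    }
    if (it >= max_iter && change >= tol) conv <- FALSE
    iters <- max(iters, it)
    gamma_star[i, ] <- g_old
    delta2_star[i, ] <- d_old
  }
  if (!conv) {
    warning("EB adjustment did not converge within ", max_iter, " iterations")
  }
  model$gamma_star <- gamma_star
  model$delta2_star <- delta2_star
  model$converged <- conv
  model$n_iter <- iters
  model
}

#' Harmonize a feature table across scanner batches
#'
#' Full ComBat pipeline: [fit_standardize()], [eb_hyperpriors()],
#' [eb_adjust()], then the back-transform
#' `yhat = sigma_hat * (Z - gamma*) / sqrt(delta2*) + alpha_hat +
#' X beta_hat`, which removes the per-batch location and scale effects while
#' re-adding the grand mean and the protected covariate structure.
#'
#' @inheritParams fit_standardize
#' @param tol,max_iter EB iteration control, see [eb_adjust()].
#' @return a list with `table` (the harmonized `feature_table`, same sample
#'   order and labels) and `model` (the fitted `combat_model`). A
#'   single-batch input is returned unchanged with a warning.
#' @export
harmonize <- function(table, covariates = "class", tol = 1e-4,
                      max_iter = 100L) {
  stopifnot(is_feature_table(table))
  if (nlevels(droplevels(table$batch)) < 2) {
    warning("single batch: nothing to harmonize, returning input unchanged")
    return(list(table = table, model = NULL))
  }
  fs <- fit_standardize(table, covariates)
  model <- eb_adjust(eb_hyperpriors(fs$model), fs$Z, table$batch,
                     tol = tol, max_iter = max_iter)
  Z <- fs$Z
  n <- nrow(Z); G <- ncol(Z)
  bi <- as.integer(factor(table$batch, levels = model$batch_levels))
  adj <- (Z - model$gamma_star[bi, , drop = FALSE]) /
    sqrt(model$delta2_star[bi, , drop = FALSE])
  stand_mean <- matrix(model$alpha_hat, n, G, byrow = TRUE)
  C <- covariate_design(table, covariates)
  if (ncol(C) > 0) stand_mean <- stand_mean + C %*% model$beta_hat
  Yhat <- adj * matrix(sqrt(model$sigma2_hat), n, G, byrow = TRUE) + stand_mean
  stopifnot(all(is.finite(Yhat)))
  out <- set_feature_values(table, Yhat)
  attr(out, "combat_model") <- model
  list(table = out, model = model)
}

#' Serialize a fitted ComBat model to JSON
#'
#' Writes every model field (estimates, hyperpriors, posteriors, batch
#' levels, iteration status) for audit.
#'
#' @param model a `combat_model`.
#' @param path output JSON path.
#' @export
write_combat_model <- function(model, path) {
  stopifnot(inherits(model, "combat_model"))
  x <- unclass(model)
  x$beta_hat <- as.data.frame(x$beta_hat)
  for (f in c("gamma_hat", "delta2_hat", "gamma_star", "delta2_star")) {
    if (!is.null(x[[f]])) x[[f]] <- as.data.frame(x[[f]])
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "string")
  invisible(path)
}
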