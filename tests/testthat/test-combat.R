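test_that("confounded designs and zero-variance features are rejected", {
  sim <- make_toy_table(n_per_batch = c(10, 10), G = 4)
  tab <- sim$table
  # covariate identical to batch membership -> unidentifiable
  tab$confound <- as.integer(tab$batch == "scanner1")
  class(tab) <- c("feature_table", "data.frame")
  expect_error(fit_standardize(tab, covariates = "confound"),
               "confounded")
  flat <- sim$table
  flat[[feature_names(flat)[2]]] <- 1
  class(flat) <- c("feature_table", "data.frame")
  expect_error(suppressWarnings(fit_standardize(flat)), "zero-variance")
})

test_that("null-effect data give gamma_hat ~ 0 and delta2_hat ~ 1", {
  sim <- simulate_features(simulation_config(
    n_per_batch = c(2000, 2000), n_features = 10, class_effect_scale = 1,
    additive_effect_scale = 0, multiplicative_effect_range = c(1, 1),
    seed = 5))
  fs <- fit_standardize(sim$table)
  expect_lt(max(abs(fs$model$gamma_hat)), 0.1)
  expect_lt(max(abs(fs$model$delta2_hat - 1)), 0.1)
  # weighted-grand-mean constraint: batch-size-weighted gamma_hat is ~0
  w <- fs$model$n_per_batch / sum(fs$model$n_per_batch)
  expect_lt(max(abs(crossprod(w, fs$model$gamma_hat))), 1e-10)
})

test_that("class effect is recovered by least squares", {
  sim <- simulate_features(simulation_config(
    n_per_batch = c(400, 400), n_features = 8, class_effect_scale = 2,
    additive_effect_scale = 0, multiplicative_effect_range = c(1, 1),
    noise_sd = 1, seed = 12))
  fs <- fit_standardize(sim$table)
  se <- 2 / sqrt(nrow(sim$table))   # sd(beta_hat) = sigma*sqrt(1/n0+1/n1)
  expect_true(all(abs(fs$model$beta_hat[1, ] - sim$truth$beta) < 3 * se))
})

test_that("hyperprior moments behave and recover a known inverse-gamma", {
  sim <- make_toy_table()
  fs <- fit_standardize(sim$table)
  m <- fs$model
  # identical gamma_hat across features -> zero prior variance
  m2 <- m
  m2$gamma_hat[1, ] <- 0.7
  h <- eb_hyperpriors(m2)
  expect_equal(unname(h$hyper_gamma_mean[1]), 0.7)
  expect_equal(unname(h$hyper_gamma_var[1]), 0)
  # permutation invariance over feature order
  perm <- sample(ncol(m$gamma_hat))
  m3 <- m
  m3$alpha_hat <- m$alpha_hat[perm]
  m3$gamma_hat <- m$gamma_hat[, perm]
  m3$delta2_hat <- m$delta2_hat[, perm]
  expect_equal(eb_hyperpriors(m3)$hyper_delta_lambda,
               eb_hyperpriors(m)$hyper_delta_lambda)
  # method-of-moments recovery from a known inverse-gamma, G = 1e4
  lambda_true <- 8; theta_true <- 6  # 4th moment finite, so MoM is stable
  withr::with_seed(88, {
    d2 <- 1 / stats::rgamma(1e4, shape = lambda_true, rate = theta_true)
  })
  mm <- structure(list(alpha_hat = numeric(1e4),
                       gamma_hat = matrix(rnorm(2e4), 2),
                       delta2_hat = rbind(d2, d2),
                       batch_levels = c("b1", "b2")),
                  class = "combat_model")
  h2 <- eb_hyperpriors(mm)
  expect_lt(abs(h2$hyper_delta_lambda[1] - lambda_true) / lambda_true, 0.05)
  expect_lt(abs(h2$hyper_delta_theta[1] - theta_true) / theta_true, 0.05)
  # fewer than 3 features is refused
  tiny <- structure(list(alpha_hat = numeric(2)), class = "combat_model")
  expect_error(eb_hyperpriors(tiny), "hyperprior error")
})

test_that("EB adjustment obeys its limiting cases and fixed-point equations", {
  sim <- make_toy_table(n_per_batch = c(30, 25), G = 12, seed = 3)
  fs <- fit_standardize(sim$table)
  h <- eb_hyperpriors(fs$model)
  # no-shrinkage limit: infinite prior variance
  h_inf <- h; h_inf$hyper_gamma_var[] <- Inf
  a_inf <- eb_adjust(h_inf, fs$Z, sim$table$batch)
  expect_equal(a_inf$gamma_star, h$gamma_hat, tolerance = 1e-12)
  # full-shrinkage limit: zero prior variance
  h0 <- h; h0$hyper_gamma_var[] <- 0
  a0 <- eb_adjust(h0, fs$Z, sim$table$batch)
  for (i in 1:2) {
    expect_equal(unname(a0$gamma_star[i, ]),
                 rep(unname(h$hyper_gamma_mean[i]), 12), tolerance = 1e-6)
  }
  # returned solution satisfies both update equations to within tol
  tol <- 1e-10
  a <- eb_adjust(h, fs$Z, sim$table$batch, tol = tol, max_iter = 5000)
  for (i in seq_along(a$batch_levels)) {
    Zi <- fs$Z[sim$table$batch == a$batch_levels[i], , drop = FALSE]
    n_i <- nrow(Zi)
    g_next <- (n_i * a$hyper_gamma_var[i] * a$gamma_hat[i, ] +
                 a$delta2_star[i, ] * a$hyper_gamma_mean[i]) /
      (n_i * a$hyper_gamma_var[i] + a$delta2_star[i, ])
    ss <- colSums(sweep(Zi, 2, g_next, "-")^2)
    d_next <- (a$hyper_delta_theta[i] + 0.5 * ss) /
      (n_i / 2 + a$hyper_delta_lambda[i] - 1)
    expect_lt(max(abs(g_next - a$gamma_star[i, ])), 1e-8)
    expect_lt(max(abs(d_next - a$delta2_star[i, ])), 1e-8)
  }
  # shrinkage ordering: posterior gamma never further from the prior mean
  for (i in seq_along(a$batch_levels)) {
    expect_true(all(abs(a$gamma_star[i, ] - a$hyper_gamma_mean[i]) <=
                      abs(a$gamma_hat[i, ] - a$hyper_gamma_mean[i]) + 1e-12))
  }
})

test_that("single-batch input is returned unchanged with a warning", {
  sim <- make_toy_table(n_per_batch = c(12, 12))
  tab <- sim$table[sim$table$batch == "scanner1", ]
  class(tab) <- c("feature_table", "data.frame")
  expect_warning(h <- harmonize(tab), "single batch")
  expect_equal(feature_matrix(h$table), feature_matrix(tab),
               tolerance = 1e-10)
})

test_that("harmonization aligns batch means and is numerically idempotent", {
  sim <- simulate_features(simulation_config(
    n_per_batch = c(300, 300, 300), n_features = 20, class_effect_scale = 1,
    additive_effect_scale = 2, multiplicative_effect_range = c(1, 1),
    seed = 44))
  h <- harmonize(sim$table)
  Y <- feature_matrix(h$table)
  cls0 <- h$table$class == 0
  for (g in sample(20, 5)) {
    ms <- tapply(Y[cls0, g], droplevels(h$table$batch[cls0]), mean)
    vs <- tapply(Y[cls0, g], droplevels(h$table$batch[cls0]), var)
    ns <- tapply(Y[cls0, g], droplevels(h$table$batch[cls0]), length)
    for (i in 1:2) for (k in (i + 1):3) {
      se <- sqrt(vs[i] / ns[i] + vs[k] / ns[k])
      expect_lt(abs(ms[i] - ms[k]), 3 * se)
    }
  }
  # approximate idempotence: a second pass only re-applies the EB shrinkage
  # residual, small relative to each feature's spread
  h2 <- harmonize(h$table, tol = 1e-6)
  sds <- apply(Y, 2, sd)
  expect_lt(max(abs(sweep(feature_matrix(h2$table) - Y, 2, sds, "/"))), 0.05)
  # labels and order untouched
  expect_identical(h$table$sample_id, sim$table$sample_id)
  expect_identical(h$table$batch, sim$table$batch)
  expect_identical(h$table$class, sim$table$class)
})

test_that("harmonization matches the established genomics implementation", {
  skip_if_not_installed("sva")
  sim <- make_toy_table(n_per_batch = c(30, 24, 20), G = 25, seed = 77,
                        additive = 1.5, mult = c(0.5, 2))
  ours <- harmonize(sim$table, tol = 1e-8, max_iter = 2000)
  mod <- stats::model.matrix(~class, sim$table)
  theirs <- suppressMessages(
    t(sva::ComBat(t(feature_matrix(sim$table)), batch = sim$table$batch,
                  mod = mod)))
  expect_lt(max(abs(feature_matrix(ours$table) - theirs)), 1e-4)
})

test_that("model JSON export contains every fitted field", {
  sim <- make_toy_table()
  h <- harmonize(sim$table)
  path <- withr::local_tempfile(fileext = ".json")
  write_combat_model(h$model, path)
  x <- jsonlite::read_json(path)
  expect_true(all(c("alpha_hat", "beta_hat", "sigma2_hat", "gamma_hat",
                    "delta2_hat", "gamma_star", "delta2_star",
                    "hyper_gamma_mean", "hyper_gamma_var",
                    "hyper_delta_lambda", "hyper_delta_theta",
                    "batch_levels", "n_iter") %in% names(x)))
})
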