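# End-to-end study replica: simulate -> (optionally extract) -> select ->
# harmonize -> assess -> evaluate -> report, driven by one configuration and
# one master seed.

#' Pipeline configuration
#'
#' Bundles the per-stage settings of the full study replica. Every stage
#' block may be omitted and defaults to the study configuration. The master
#' `seed` expands into per-stage seeds by a fixed counter scheme
#' (`stage_seed = (seed + 1009 * stage_index) mod 2^31 - 1`), so stages are
#' independently reproducible.
#'
#' @param simulation arguments for [simulation_config()].
#' @param extraction list with `n_levels`, `distance`, `alpha` (volume path).
#' @param selection list with `penalty`, `n_keep`.
#' @param combat list with `tol`, `max_iter`.
#' @param evaluation list with `ratio`, `k_folds`.
#' @param seed master integer seed.
#' @param output_dir directory for all artifacts.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(simulation = list(),
                            extraction = list(n_levels = 25L, distance = 1L,
                                              alpha = 0L),
                            selection = list(penalty = 0.1, n_keep = 20L),
                            combat = list(tol = 1e-4, max_iter = 100L),
                            evaluation = list(ratio = 0.8, k_folds = 5L),
                            seed = 1L,
                            output_dir = tempfile("radcombat_run_")) {
  structure(list(simulation = simulation, extraction = extraction,
                 selection = selection, combat = combat,
                 evaluation = evaluation, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(pipeline_config, x)
}

#' @rdname read_pipeline_config
#' @param config a [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

stage_seed <- function(master, stage_index) {
  as.integer((as.numeric(master) + 1009 * stage_index) %% (2^31 - 1))
}

#' Run the full harmonization study replica
#'
#' Stages, in order: simulate a multi-scanner feature table with known ground
#' truth; screen features by lasso on the unharmonized data; harmonize with
#' the class covariate protected; assess batch effects (per-feature ANOVA,
#' PCA silhouette, distribution summaries) before and after; evaluate the
#' five classifiers on both arms; write every intermediate artifact plus a
#' manifest with file hashes and seeds.
#'
#' @param config a [pipeline_config()].
#' @return the manifest (invisibly also written as `manifest.json`): artifact
#'   paths, md5 hashes, per-stage seeds, record counts and headline numbers.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$output_dir, f)
  artifacts <- character(0)
  note <- function(msg, ...) message(sprintf(paste0("[radcombat] ", msg), ...))

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
  }

  # --- simulate ---
  sim_args <- utils::modifyList(config$simulation,
                                list(seed = stage_seed(config$seed, 1L)))
  sim <- run_stage("simulate", {
    cfg <- do.call(simulation_config, sim_args)
    simulate_features(cfg)
  })
  write_feature_csv(sim$table, out("features.csv"))
  artifacts <- c(artifacts, out("features.csv"))
  note("simulate: %d samples x %d features in %d batches",
       nrow(sim$table), length(feature_names(sim$table)),
       nlevels(sim$table$batch))

  # --- select (on the unharmonized table; the feature set is held fixed
  # across both arms) ---
  sel <- run_stage("select", {
    lasso_select(sim$table, penalty = config$selection$penalty,
                 n_keep = config$selection$n_keep)
  })
  jsonlite::write_json(
    list(selected_names = sel$selected_names,
         coefficients = as.list(sel$coefficients),
         penalty = sel$penalty, n_requested = sel$n_requested),
    out("selected.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  artifacts <- c(artifacts, out("selected.json"))
  note("select: %d features retained", length(sel$selected_names))

  # --- harmonize ---
  harm <- run_stage("harmonize", harmonize(sim$table, covariates = "class",
                                           tol = config$combat$tol,
                                           max_iter = config$combat$max_iter))
  write_feature_csv(harm$table, out("harmonized.csv"))
  write_combat_model(harm$model, out("model.json"))
  artifacts <- c(artifacts, out("harmonized.csv"), out("model.json"))
  note("harmonize: EB %s in %d iterations",
       if (harm$model$converged) "converged" else "did NOT converge",
       harm$model$n_iter)

  # --- assess ---
  assess <- run_stage("assess", {
    before <- anova_by_batch(sim$table, sel$selected_names)
    after <- anova_by_batch(harm$table, sel$selected_names)
    sil_before <- batch_silhouette(pca_project(sim$table))
    sil_after <- batch_silhouette(pca_project(harm$table))
    list(before = before, after = after,
         sil_before = sil_before, sil_after = sil_after)
  })
  anova_tbl <- data.frame(feature_name = assess$before$feature_name,
                          p_without = assess$before$p_value,
                          p_with = assess$after$p_value,
                          f_without = assess$before$f_statistic,
                          f_with = assess$after$f_statistic)
  utils::write.csv(anova_tbl, out("anova.csv"), row.names = FALSE)
  summaries <- distribution_summary(sim$table, sel$selected_names[1])
  jsonlite::write_json(list(
    silhouette = list(without = assess$sil_before, with = assess$sil_after),
    example_feature_summary = summaries), out("summaries.json"),
    auto_unbox = TRUE, digits = NA)
  artifacts <- c(artifacts, out("anova.csv"), out("summaries.json"))
  note("assess: %d/%d features with p<0.05 before, %d after; silhouette %.3f -> %.3f",
       sum(assess$before$p_value < 0.05), nrow(assess$before),
       sum(assess$after$p_value < 0.05), assess$sil_before, assess$sil_after)

  # --- evaluate ---
  eval_seed <- stage_seed(config$seed, 2L)
  evaluation <- run_stage("evaluate", {
    specs <- default_model_specs(seed = eval_seed)
    tab_wo <- subset_features(sim$table, sel$selected_names)
    tab_wi <- subset_features(harm$table, sel$selected_names)
    rep_wo <- evaluate_models(tab_wo, specs, k = config$evaluation$k_folds,
                              ratio = config$evaluation$ratio, seed = eval_seed)
    rep_wi <- evaluate_models(tab_wi, specs, k = config$evaluation$k_folds,
                              ratio = config$evaluation$ratio, seed = eval_seed)
    list(without = rep_wo, with = rep_wi,
         comparison = compare_arms(rep_wo, rep_wi))
  })
  eval_json <- list(
    deltas = evaluation$comparison$deltas,
    summaries = lapply(
      stats::setNames(nm = setdiff(names(evaluation$without), ".split")),
      function(m) list(without = evaluation$without[[m]]$cv$summary,
                       with = evaluation$with[[m]]$cv$summary)),
    importance_spearman = lapply(evaluation$comparison$importance_change,
                                 function(x) x$spearman))
  jsonlite::write_json(eval_json, out("eval.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  artifacts <- c(artifacts, out("eval.json"))
  note("evaluate: mean AUC delta %.3f over %d models",
       mean(evaluation$comparison$deltas$delta[
         evaluation$comparison$deltas$metric == "auc"]),
       length(setdiff(names(evaluation$without), ".split")))

  manifest <- list(
    package_version = as.character(utils::packageVersion("radcombat")),
    master_seed = config$seed,
    stage_seeds = list(simulate = stage_seed(config$seed, 1L),
                       evaluate = eval_seed),
    n_samples = nrow(sim$table),
    n_features = length(feature_names(sim$table)),
    n_selected = length(sel$selected_names),
    artifacts = as.list(stats::setNames(unname(tools::md5sum(artifacts)),
                                        basename(artifacts))))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(manifest, list(results = list(
    anova = anova_tbl,
    silhouette = c(without = assess$sil_before, with = assess$sil_after),
    deltas = evaluation$comparison$deltas))))
}
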