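# radcombat

Scanner-manufacturer batch effects are one of the main obstacles to
multi-center radiomics: texture and intensity features computed from CT
images shift in location and scale depending on which scanner produced the
image, which corrupts downstream statistics and machine-learning models.
`radcombat` implements parametric empirical-Bayes **ComBat harmonization**
for radiomic feature tables, together with everything needed to study it end
to end: a synthetic multi-scanner generator with known ground truth, an
IBSI-style texture-feature extractor, lasso feature screening, batch-effect
assessment (per-feature ANOVA, PCA, distribution summaries) and a
five-classifier evaluation harness comparing performance before vs after
harmonization.

It is aimed at imaging scientists who want a tested, auditable R
implementation of the harmonization workflow, and at methodologists who want
a controlled sandbox in which the ground truth of every batch effect is
known.

## The model

The value of radiomic feature *g* for sample *j* acquired on scanner batch
*i* is modeled as

    y_ijg = alpha_g + X beta_g + gamma_ig + delta_ig * eps_ijg

where `alpha_g` is the overall feature level, `X` the design of protected
covariates (here the binary texture class), `gamma_ig` and `delta_ig` the
additive and multiplicative scanner effects, and
`eps_ijg ~ N(0, sigma_g^2)`. After least-squares estimation and
standardization, the per-batch effect estimates are shrunk across features by
empirical-Bayes priors (normal on `gamma`, inverse-gamma on `delta^2`,
hyperparameters by method of moments) and removed:

    yhat_ijg = (y_ijg - alpha_g - X beta_g - gamma*_ig) / delta*_ig
               + alpha_g + X beta_g

so scanner location/scale differences vanish while the protected class
signal is re-added. The implementation is authored from these equations and
cross-checked in the test suite against an independent equation-level
reference and against the genomics implementation in `sva`.

## Worked example

```r
library(radcombat)

# 3 scanner batches (53/42/40 samples), 100 features, strong batch effects
sim <- simulate_features(simulation_config(seed = 42))
sim$table
#> <feature_table> 135 samples x 100 features; batches: scanner1, scanner2, scanner3

a0 <- anova_by_batch(sim$table)
sum(a0$p_value < 0.05)        # 96 of 100 features show scanner differences

h <- harmonize(sim$table)     # class label protected by default
h$model
#> <combat_model> 3 batches (scanner1, scanner2, scanner3), 100 features;
#>   EB-adjusted (converged in 3 iterations)

a1 <- anova_by_batch(h$table)
sum(a1$p_value < 0.05)        # 0 of 100; min p = 0.866
batch_silhouette(pca_project(sim$table))  #  0.856 (batches separate)
batch_silhouette(pca_project(h$table))    # -0.030 (batches mixed)

sel <- lasso_select(sim$table, penalty = 0.1, n_keep = 20)
spec <- model_spec("random_forest", seed = 42)
cross_validate(spec, subset_features(sim$table, sel), seed = 42)$summary
cross_validate(spec, subset_features(h$table, sel), seed = 42)$summary
#> random-forest 5-fold AUC: 0.997 (without) vs 0.999 (with ComBat)
```

Reading the numbers: before harmonization nearly every feature differs
significantly across scanners (ANOVA p < 0.05) and the batches form distinct
clusters in PCA space (silhouette 0.86); after harmonization no feature
shows a scanner difference (all p > 0.05) and the batches are fully mixed
(silhouette near 0), while the class signal used by the classifiers is
preserved.

A labeled two-texture phantom volume path is also available:
`simulate_phantom()` → `write_nifti()` / `read_nifti()` → `extract_all()`
computes 86 first-order, GLCM, GLRLM, GLSZM and GLDM features per ROI cube.
The whole study replica (simulate → screen → harmonize → assess → evaluate)
runs from one config via `run_pipeline()`, or from the shell via
`inst/cli/radcombat.R`.

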