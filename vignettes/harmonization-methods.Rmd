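---
title: "Methods: empirical-Bayes harmonization of multi-scanner radiomic features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: empirical-Bayes harmonization of multi-scanner radiomic features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Radiomic features — intensity statistics and texture-matrix summaries of a
region of interest in a CT image — are sensitive to which scanner produced
the image. When cohorts are pooled across manufacturers, each scanner group
("batch") shifts the features in location and scale. `radcombat` implements
the standard remedy, ComBat harmonization, and surrounds it with a
controlled synthetic test bed so that every claim about the method can be
checked against known ground truth.

# The generative and adjustment model

We assume feature $g$ of sample $j$ on scanner batch $i$ follows

$$y_{ijg} = \alpha_g + X\beta_g + \gamma_{ig} + \delta_{ig}\,\varepsilon_{ijg},
\qquad \varepsilon_{ijg} \sim N(0, \sigma_g^2),$$

with a protected covariate design $X$ (here the binary texture class),
additive scanner effects $\gamma_{ig}$ and multiplicative effects
$\delta_{ig}$. `fit_standardize()` estimates $\alpha_g$, $\beta_g$ and the
per-batch means by least squares under the constraint that batch effects
average to zero with batch-size weights (so harmonized data land on the
pooled overall location rather than on a designated reference batch), pools
the residual variance $\hat\sigma_g^2$ with denominator $n$, and forms
$Z_{ijg} = (y_{ijg} - \hat\alpha_g - X\hat\beta_g)/\hat\sigma_g$. The raw
batch-effect estimates are the per-batch mean ($\hat\gamma_{ig}$) and
variance ($\hat\delta^2_{ig}$, denominator $n_i - 1$) of $Z$.

`eb_hyperpriors()` fits the empirical priors across features within each
batch by method of moments: $\gamma_{ig} \sim N(\bar\gamma_i, \tau_i^2)$
with $\bar\gamma_i, \tau_i^2$ the mean and variance of $\hat\gamma_{ig}$
over $g$, and $\delta^2_{ig} \sim \text{InvGamma}(\lambda_i, \theta_i)$
with $\lambda_i = (2s^2 + m^2)/s^2$, $\theta_i = (m s^2 + m^3)/s^2$ from
the empirical mean $m$ and variance $s^2$ of $\hat\delta^2_{ig}$. A
moment-matching caveat verified in the tests: the recovery of
$(\lambda, \theta)$ from simulated draws is only stable when the prior's
fourth moment exists ($\lambda > 4$); heavy-tailed priors inflate the
sampling error of $s^2$.

`eb_adjust()` iterates the conditional posterior updates

$$\gamma^*_{ig} = \frac{n_i \tau_i^2 \hat\gamma_{ig} + \delta^{2*}_{ig}
\bar\gamma_i}{n_i \tau_i^2 + \delta^{2*}_{ig}}, \qquad
\delta^{2*}_{ig} = \frac{\theta_i + \tfrac12 \sum_j (Z_{ijg} -
\gamma^*_{ig})^2}{n_i/2 + \lambda_i - 1}$$

until the largest absolute parameter change falls below `tol` (default
`1e-4`, `max_iter = 100`; non-convergence is recorded and warned about,
never silent). Degenerate hyperpriors short-circuit deterministically:
$\tau^2 = 0$ gives full shrinkage to $\bar\gamma_i$; an infinite $\tau^2$
or a zero-variance $\hat\delta^2$ distribution leaves the raw estimates
untouched. Finally `harmonize()` back-transforms

$$\hat y_{ijg} = \hat\sigma_g \frac{Z_{ijg} - \gamma^*_{ig}}
{\sqrt{\delta^{2*}_{ig}}} + \hat\alpha_g + X\hat\beta_g.$$

Only the parametric form is implemented; nonparametric prior estimation and
reference-batch/longitudinal modes are out of scope. The class label is
always carried as a protected covariate — dropping it would remove the
biological signal along with the scanner effect. The test suite checks the
implementation against an independently coded, per-feature-loop reference
of the same equations (agreement to 1e-6) and against the genomics
implementation in `sva` (agreement to ~1e-6 at tight tolerance; asserted at
1e-4 because `sva`'s internal stopping rule is fixed).

**Approximate idempotence.** Harmonizing already-harmonized data is not an
exact no-op: the EB step shrinks the (now nearly null) batch effects toward
their cross-feature means, so a second pass re-applies a shrinkage residual.
At 20 features and 300 samples per batch this residual is about 3% of a
feature's spread, shrinking as the number of samples grows. The tests assert
it stays below 5% of each feature's standard deviation; the reference
implementation behaves identically, so this is a property of empirical-Bayes
ComBat itself.

# The synthetic generator

`simulation_config()` defaults define the study conditions: 3 batches of
53/42/40 samples (the retained Siemens/Philips/GE cohort sizes of the
phantom design the generator emulates), 100 features, additive effect scale
1.5, multiplicative effect range (0.5, 2), unit noise, and classes balanced
within each batch (one ROI per cartridge texture per cohort — a paired
design). Ground-truth parameters are drawn from the same families the EB
step assumes ($\alpha_g \sim N(0,1)$, $\beta_g \sim N(0,
\text{class\_effect\_scale}^2)$, $\gamma_{ig} \sim N(0,
\text{additive\_effect\_scale}^2)$, $\delta_{ig} \sim
U(\text{range})$), which is deliberate: it makes parameter-recovery tests
meaningful, and it also means passing tests demonstrate behavior *under the
model's own assumptions*, not robustness to misspecification. Real
scanner effects need not be additive/multiplicative per feature, need not
share a prior across features, and include correlated effects
(reconstruction kernel, slice thickness) that the generator folds into
$\gamma/\delta$ rather than modeling separately. The class-effect scale
default of 1 ("class effect comparable to noise") makes the two textures
clearly separable after feature screening; classifier AUCs on synthetic
data therefore saturate near 1 and before/after comparisons mostly show
ties and small positive shifts rather than the larger gains reported on
real phantom data.

The volume path (`simulate_phantom()`) packs an even number of identical
ROI cubes (side ≥ 5 voxels, one-voxel gaps) into a grid: class 0 is filled
with speckle (white noise smoothed by a 3×3×3 box kernel, emulating a
rubber-particle cartridge), class 1 with a thresholded sum of three
phase-shifted sinusoids plus noise (a honeycomb-like periodic pattern).
These textures are cheap, parameterized and separable by construction; they
do not emulate CT acquisition physics, DICOM metadata or reconstruction
kernels.

# Texture features

`extract_all()` applies, per ROI cube: Min-Max normalization to [0, 1]
(constant ROI ↦ all zeros), equal-width discretization into `n_levels`
bins (default 25, read as a bin *count*: a bin width of 25 on [0, 1] data
would be vacuous; the value 1.0 closes the top bin), then five families
totalling 86 features — 18 first-order ("Percentile" realized as the
10th/90th pair), 22 GLCM, 16 GLRLM, 16 GLSZM, 14 GLDM. Conventions, chosen
to match common IBSI-compliant extractors and documented per feature:

- GLCM: symmetric pairing, distance 1, counts pooled over the 13 unique 3D
  directions into a single matrix before normalization. Correlation on a
  zero-variance matrix is 1; Imc1/Imc2 are 0 when marginal entropies vanish.
- GLRLM: runs pooled over the 13 directions into one matrix; Run Percentage
  divides the pooled run count by (directions × voxels).
- GLSZM: zones are 26-connected equal-level components.
- GLDM: `alpha = 0`; the dependence size counts the center voxel plus its
  dependent neighbors (so sizes start at 1 and small-dependence emphases
  never divide by zero).
- First-order Skewness/Kurtosis are 0 on constant ROIs; Variance is the
  population moment.

Every matrix builder is verified exactly against brute-force enumeration
oracles on random 4×4×1 arrays, and all matrix features are translation
invariant by construction (tested by duplicating a cube at another
position).

# Screening, assessment, evaluation

Feature screening is an L1-penalized linear fit of the class label on the
internally standardized features at fixed penalty 0.1 (1/(2n)·RSS
parameterization, 1000 iterations), ranked by |coefficient| with ties broken
lexicographically. Selection runs once, on the unharmonized table, and the
same names are used in both arms so before/after comparisons hold the
feature set fixed; whether screening should precede or follow harmonization
is genuinely open, and this choice is the reproducible one. At the fixed
penalty the realized selection can be smaller than the 20 requested: only
nonzero-coefficient features are ever returned.

Batch-effect assessment is per-feature one-way fixed-effects ANOVA computed
from the sums-of-squares formulas (verified against `aov` to 1e-10),
reported unadjusted to match per-feature reporting conventions with a
Benjamini–Hochberg column alongside; the degenerate zero-within-variance
case reports the smallest positive double rather than 0. PCA is computed on
the centered, unit-variance matrix with a deterministic sign convention
(largest-magnitude loading positive); batch separability is summarized by
the mean silhouette of batch labels in 2-component score space.
Distribution summaries use type-7 (linear interpolation) quartiles, Tukey
whiskers, and Gaussian kernel densities (Silverman bandwidth) on a shared
256-point grid padded by 4 bandwidths so each curve integrates to 1.

The evaluation harness fixes the five model configurations: lasso (penalty
0.1, thresholded at 0.5 — the "lasso classifier" is thresholded regression,
not L1-logistic, which the configuration leaves ambiguous), L2 logistic
regression (ridge with $\lambda = 1/(Cn)$, $C = 1$), random forest (100
trees, depth 8), RBF SVM (cost 2, kernel coefficient
$1/(p\,\mathrm{var}(x))$), and a 5-hidden-layer ReLU network trained by
minibatch SGD (learning rate 0.01, 200 epochs). Hidden-layer widths are not
part of the original configuration; 32 units per layer is the package
default and configurable. The network is implemented directly in matrix
algebra within the package. Splits and folds are stratified by class;
standardization always uses training-fold statistics only (a leakage test
corrupts held-out labels and asserts unchanged fits); CV confidence
intervals use the normal approximation mean ± 1.96·sd/√k, clipped to
[0, 1] — a pragmatic convention at k = 5, not an exact interval.

One known limitation, faithful to the workflow being replicated:
harmonization for the "with" arm is fit on the full table *before*
splitting, so the held-out fold influences the harmonization parameters. A
strict mode that re-fits ComBat inside every training fold is not
implemented; on synthetic data the effect is negligible because the batch
effects are orthogonal to the class by design, but for real predictive
claims the strict order would be the defensible one.

# Problem sizes and determinism

All randomness flows through explicit integer seeds scoped with
`withr::with_seed`; no function perturbs the caller's RNG state. The
pipeline expands one master seed into per-stage seeds by a fixed counter
scheme recorded in the manifest. Test problem sizes were chosen to keep the
statistical assertions sharp at small cost: 20 replicate simulations of the
135 × 100 study-sized table for the distributional claims, 500 features for
parameter recovery (so "within 3 standard errors" can be asserted as a
≥ 98–99% coverage rate rather than a flaky all-or-nothing), 10⁴ draws for
moment-recovery checks, and 4×4×1 arrays for exhaustive texture-matrix
enumeration.
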