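# Batch-effect assessment: per-feature one-way ANOVA across scanner batches,
# PCA of the standardized feature table, and per-group distribution
# summaries. These quantify how much scanner signal remains before vs after
# harmonization.

#' Per-feature one-way ANOVA across batches
#'
#' Classical fixed-effects one-way F test of batch differences, computed
#' feature by feature from the between/within sums of squares. p-values are
#' deliberately unadjusted (per-feature reporting); a Benjamini-Hochberg
#' column is added for transparency. When the within-group variance is zero
#' while groups differ, the p-value is reported as the smallest positive
#' double (underflow-safe convention) rather than 0.
#'
#' @param table a [feature_table()] (>= 2 batches, >= 2 samples each).
#' @param features optional feature subset (names or a `selection_result`);
#'   defaults to all features.
#' @return a `data.frame` with columns `feature_name`, `f_statistic`,
#'   `p_value`, `p_adjusted`, `df_between`, `df_within`.
#' @export
anova_by_batch <- function(table, features = NULL) {
  validate_for_harmonization(table)
  if (!is.null(features)) table <- subset_features(table, features)
  Y <- feature_matrix(table)
  g <- droplevels(table$batch)
  k <- nlevels(g)
  n <- nrow(Y)
  df_b <- k - 1L
  df_w <- n - k
  grand <- colMeans(Y)
  ss_between <- numeric(ncol(Y))
  ss_within <- numeric(ncol(Y))
  for (lev in levels(g)) {
    Yi <- Y[g == lev, , drop = FALSE]
    mi <- colMeans(Yi)
    ss_between <- ss_between + nrow(Yi) * (mi - grand)^2
    ss_within <- ss_within + colSums(sweep(Yi, 2, mi)^2)
  }
  f <- (ss_between / df_b) / (ss_within / df_w)
  # zero within-group variance: infinite F if groups differ, 0/0 if identical
  f[ss_within == 0 & ss_between == 0] <- 0
  p <- stats::pf(f, df_b, df_w, lower.tail = FALSE)
  p[is.infinite(f)] <- .Machine$double.xmin
  f[is.infinite(f)] <- .Machine$double.xmax
  data.frame(feature_name = colnames(Y),
             f_statistic = unname(f),
             p_value = unname(p),
             p_adjusted = stats::p.adjust(unname(p), method = "BH"),
             df_between = df_b,
             df_within = df_w,
             stringsAsFactors = FALSE)
}

#' PCA projection of a feature table
#'
#' Principal components of the centered, unit-variance-scaled feature matrix.
#' Constant features are dropped with a warning before the decomposition.
#' The sign of each component is fixed so that its largest-magnitude loading
#' is positive.
#'
#' @param table a [feature_table()].
#' @param n_components number of components to return (default 2).
#' @return a list of class `"pca_projection"` with `scores` (sample x
#'   component), `explained_variance_ratio`, `loadings` (feature x
#'   component), `batch`, `class`.
#' @export
pca_project <- function(table, n_components = 2L) {
  stopifnot(is_feature_table(table))
  Y <- feature_matrix(table)
  sds <- apply(Y, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant feature(s): ",
            paste(colnames(Y)[sds == 0], collapse = ", "))
    Y <- Y[, sds > 0, drop = FALSE]
  }
  if (ncol(Y) < n_components) {
    stop("need at least ", n_components, " non-constant features")
  }
  pc <- stats::prcomp(Y, center = TRUE, scale. = TRUE)
  nc <- min(n_components, ncol(pc$x))
  scores <- pc$x[, seq_len(nc), drop = FALSE]
  loadings <- pc$rotation[, seq_len(nc), drop = FALSE]
  for (j in seq_len(nc)) {        # deterministic sign convention
    top <- which.max(abs(loadings[, j]))
    if (loadings[top, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = scores,
                 explained_variance_ratio = evr[seq_len(nc)],
                 loadings = loadings,
                 batch = table$batch,
                 class = table$class),
            class = "pca_projection")
}

#' Batch separability in PCA score space
#'
#' Mean silhouette width of the batch labels over the PCA scores: near 1
#' means batches form distinct clusters (strong batch effect), near 0 or
#' below means batches are mixed. Used to quantify the before/after
#' harmonization contrast seen in PCA plots.
#'
#' @param projection a `pca_projection`.
#' @return mean silhouette width (numeric scalar).
#' @export
batch_silhouette <- function(projection) {
  stopifnot(inherits(projection, "pca_projection"))
  sil <- cluster::silhouette(as.integer(projection$batch),
                             stats::dist(projection$scores))
  mean(sil[, "sil_width"])
}

#' Per-group distribution summaries of selected features
#'
#' For each feature and group: quartiles (linear-interpolation convention,
#' R type 7), Tukey whiskers (most extreme values within 1.5 IQR of the
#' box), and a Gaussian kernel density (Silverman's rule-of-thumb bandwidth)
#' evaluated on a fixed 256-point grid spanning the feature's overall range,
#' so group curves are directly comparable.
#'
#' @param table a [feature_table()].
#' @param features feature names (or a `selection_result`); defaults to all.
#' @param group_by grouping label column, `"batch"` (default) or `"class"`.
#' @return nested list: `result[[feature]][[group]]` with elements
#'   `quartiles`, `whiskers`, `density` (list with `x`, `y`), `n`; plus a
#'   `quartile_type` metadata entry per feature.
#' @export
distribution_summary <- function(table, features = NULL, group_by = "batch") {
  stopifnot(is_feature_table(table), group_by %in% c("batch", "class"))
  if (!is.null(features)) table <- subset_features(table, features)
  groups <- factor(table[[group_by]])
  if (any(table(groups) == 0)) stop("input error: empty group")
  out <- list()
  for (f in feature_names(table)) {
    v <- table[[f]]
    # shared grid: feature range padded by 4 kernel bandwidths so every
    # group's density mass is captured and curves are comparable
    bws <- vapply(levels(groups), function(lev) {
      x <- v[groups == lev]
      if (length(x) >= 2 && stats::sd(x) > 0) stats::bw.nrd0(x) else 0
    }, numeric(1))
    pad <- 4 * max(bws, 0)
    grid <- seq(min(v) - pad, max(v) + pad, length.out = 256)
    per_group <- list()
    for (lev in levels(groups)) {
      x <- v[groups == lev]
      qs <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
      iqr <- qs[3] - qs[1]
      lo <- min(x[x >= qs[1] - 1.5 * iqr])
      hi <- max(x[x <= qs[3] + 1.5 * iqr])
      dens <- if (length(x) >= 2 && stats::sd(x) > 0) {
        d <- stats::density(x, bw = "nrd0", n = 256,
                            from = grid[1], to = grid[256])
        list(x = d$x, y = d$y)
      } else {
        list(x = grid, y = rep(NA_real_, 256))
      }
      per_group[[lev]] <- list(quartiles = qs, whiskers = c(lo, hi),
                               density = dens, n = length(x))
    }
    out[[f]] <- c(per_group, list(quartile_type = "linear interpolation (type 7)"))
  }
  out
}
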