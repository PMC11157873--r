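# Radiomic feature formulas for the five families. Conventions for degenerate
# ROIs (constant intensity, single voxel) are stated per feature; no feature
# ever returns NaN on a valid ROI.

log2_safe <- function(p) ifelse(p > 0, log2(p), 0)

new_feature_vector <- function(values) {
  stopifnot(!is.null(names(values)), !anyDuplicated(names(values)))
  if (any(!is.finite(values))) {
    stop("internal error: non-finite feature value in ",
         paste(names(values)[!is.finite(values)], collapse = ", "))
  }
  values
}

#' First-order intensity features
#'
#' Statistics of the raw (normalized) ROI intensities, plus histogram
#' Entropy/Uniformity computed on the discretized levels. Percentile is
#' realized as the 10th and 90th percentile pair; Kurtosis is the
#' non-excess ratio `m4/m2^2`. On a constant ROI, Skewness and Kurtosis are 0
#' by convention and Variance is 0.
#'
#' @param roi_voxels numeric in-ROI voxel values (vector or array; `NA` =
#'   background).
#' @param levels a `discretized_roi` of the same ROI (for Entropy and
#'   Uniformity); computed with 25 levels from the normalized voxels when
#'   omitted.
#' @param voxel_volume physical volume of one voxel in mm^3 (for Total
#'   Energy).
#' @return named numeric feature vector.
#' @export
firstorder_features <- function(roi_voxels, levels = NULL, voxel_volume = 1) {
  x <- roi_voxels[!is.na(roi_voxels)]
  if (length(x) == 0) stop("input error: empty ROI")
  if (is.null(levels)) levels <- discretize(minmax_normalize(roi_voxels), 25L)
  lv <- levels$levels[levels$levels > 0L]
  p <- tabulate(lv, nbins = levels$n_levels) / length(lv)
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  q <- stats::quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE)
  inner <- x[x >= q[1] & x <= q[5]]
  skew <- if (m2 > 0) mean((x - mu)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((x - mu)^4) / m2^2 else 0
  new_feature_vector(c(
    `10Percentile` = q[1],
    `90Percentile` = q[5],
    Energy = sum(x^2),
    Entropy = -sum(p * log2_safe(p)),
    InterquartileRange = q[4] - q[2],
    Kurtosis = kurt,
    Maximum = max(x),
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    Mean = mu,
    Median = q[3],
    Minimum = min(x),
    Range = max(x) - min(x),
    RobustMeanAbsoluteDeviation = mean(abs(inner - mean(inner))),
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = skew,
    TotalEnergy = voxel_volume * sum(x^2),
    Uniformity = sum(p^2),
    Variance = m2))
}

#' GLCM texture features
#'
#' The 22 co-occurrence features computed from a normalized symmetric GLCM.
#' Degenerate conventions: Correlation is 1 when a marginal variance is 0
#' (single gray level); Imc1 is 0 and Imc2 is 0 when the marginal entropies
#' vanish.
#'
#' @param m a `texture_matrix` of kind `"GLCM"` (normalized), from [glcm()].
#' @return named numeric feature vector.
#' @export
glcm_features <- function(m) {
  stopifnot(inherits(m, "texture_matrix"), m$kind == "GLCM")
  p <- m$matrix
  if (!m$normalized) p <- p / sum(p)
  ng <- nrow(p)
  i <- seq_len(ng)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(i * px); muy <- sum(i * py)
  sigx <- sqrt(sum((i - mux)^2 * px)); sigy <- sqrt(sum((i - muy)^2 * py))
  ii <- matrix(i, ng, ng); jj <- t(ii)
  # diagonal (difference) and cross-diagonal (sum) probabilities
  kdiff <- 0:(ng - 1)
  pdiff <- vapply(kdiff, function(k) sum(p[abs(ii - jj) == k]), numeric(1))
  ksum <- 2:(2 * ng)
  psum <- vapply(ksum, function(k) sum(p[(ii + jj) == k]), numeric(1))
  autoc <- sum(ii * jj * p)
  contrast <- sum((ii - jj)^2 * p)
  corr <- if (sigx * sigy > 0) (autoc - mux * muy) / (sigx * sigy) else 1
  da <- sum(kdiff * pdiff)
  hxy <- -sum(p * log2_safe(p))
  hx <- -sum(px * log2_safe(px)); hy <- -sum(py * log2_safe(py))
  pxy <- outer(px, py)
  hxy1 <- -sum(p * log2_safe(pxy))
  hxy2 <- -sum(pxy * log2_safe(pxy))
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(pmax(1 - exp(-2 * (hxy2 - hxy)), 0))
  offdiag <- abs(ii - jj) > 0
  new_feature_vector(c(
    Autocorrelation = autoc,
    JointAverage = mux,
    ClusterProminence = sum((ii + jj - mux - muy)^4 * p),
    ClusterShade = sum((ii + jj - mux - muy)^3 * p),
    ClusterTendency = sum((ii + jj - mux - muy)^2 * p),
    Contrast = contrast,
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(pdiff * log2_safe(pdiff)),
    DifferenceVariance = sum((kdiff - da)^2 * pdiff),
    JointEnergy = sum(p^2),
    JointEntropy = hxy,
    Imc1 = imc1,
    Imc2 = imc2,
    Idm = sum(p / (1 + (ii - jj)^2)),
    Idmn = sum(p / (1 + ((ii - jj) / ng)^2)),
    Id = sum(p / (1 + abs(ii - jj))),
    Idn = sum(p / (1 + abs(ii - jj) / ng)),
    InverseVariance = sum(p[offdiag] / (ii - jj)[offdiag]^2),
    MaximumProbability = max(p),
    SumEntropy = -sum(psum * log2_safe(psum)),
    SumSquares = sum((ii - mux)^2 * p)))
}

# Shared skeleton for the three level-by-size count matrices (runs, zones,
# dependencies): i = gray level, j = run length / zone size / dependence size.
level_size_features <- function(counts, np, names_map, extra = NULL) {
  nr <- sum(counts)
  p <- counts / nr
  ng <- nrow(counts); nj <- ncol(counts)
  i <- seq_len(ng); j <- seq_len(nj)
  ii <- matrix(i, ng, nj); jj <- matrix(j, ng, nj, byrow = TRUE)
  pg <- rowSums(p); pj <- colSums(p)
  mug <- sum(i * pg); muj <- sum(j * pj)
  vals <- c(
    gln = sum(rowSums(counts)^2) / nr,
    glnn = sum(rowSums(counts)^2) / nr^2,
    glv = sum(p * (ii - mug)^2),
    hgl = sum(p * ii^2),
    lgl = sum(p / ii^2),
    sjn = sum(colSums(counts)^2) / nr,
    sjnn = sum(colSums(counts)^2) / nr^2,
    small = sum(p / jj^2),
    large = sum(p * jj^2),
    small_high = sum(p * ii^2 / jj^2),
    small_low = sum(p / (ii^2 * jj^2)),
    large_high = sum(p * ii^2 * jj^2),
    large_low = sum(p * jj^2 / ii^2),
    jv = sum(p * (jj - muj)^2),
    entropy = -sum(p * log2_safe(p)),
    pct = nr / np)
  out <- vals[names_map]
  names(out) <- names(names_map)
  if (!is.null(extra)) out <- c(out, extra)
  new_feature_vector(out)
}

#' GLRLM run-length features
#'
#' The 16 run-length features computed from the run counts pooled over the 13
#' unique 3D directions into a single matrix. Run Percentage uses the pooled
#' run count divided by (number of directions x number of in-ROI voxels).
#'
#' @param roi a `discretized_roi` (or integer level array).
#' @param directions direction triples; defaults to the 13 unique 3D
#'   directions.
#' @return named numeric feature vector.
#' @export
glrlm_features <- function(roi, directions = NULL) {
  roi <- as_discretized(roi)
  if (is.null(directions)) directions <- unique_directions_3d()
  counts <- glrlm_matrix(roi, directions)
  np <- roi$voxel_count * nrow(as.matrix(directions))
  level_size_features(counts, np, c(
    GrayLevelNonUniformity = "gln",
    GrayLevelNonUniformityNormalized = "glnn",
    GrayLevelVariance = "glv",
    HighGrayLevelRunEmphasis = "hgl",
    LongRunEmphasis = "large",
    LongRunHighGrayLevelEmphasis = "large_high",
    LongRunLowGrayLevelEmphasis = "large_low",
    LowGrayLevelRunEmphasis = "lgl",
    RunEntropy = "entropy",
    RunLengthNonUniformity = "sjn",
    RunLengthNonUniformityNormalized = "sjnn",
    RunPercentage = "pct",
    RunVariance = "jv",
    ShortRunEmphasis = "small",
    ShortRunHighGrayLevelEmphasis = "small_high",
    ShortRunLowGrayLevelEmphasis = "small_low"))
}

#' GLSZM size-zone features
#'
#' The 16 size-zone features; zones are 26-connected components of equal
#' gray level. Zone Percentage is the zone count divided by the in-ROI voxel
#' count.
#'
#' @param roi a `discretized_roi` (or integer level array).
#' @return named numeric feature vector.
#' @export
glszm_features <- function(roi) {
  roi <- as_discretized(roi)
  counts <- glszm_matrix(roi)
  level_size_features(counts, roi$voxel_count, c(
    GrayLevelNonUniformity = "gln",
    GrayLevelNonUniformityNormalized = "glnn",
    GrayLevelVariance = "glv",
    HighGrayLevelZoneEmphasis = "hgl",
    LargeAreaEmphasis = "large",
    LargeAreaHighGrayLevelEmphasis = "large_high",
    LargeAreaLowGrayLevelEmphasis = "large_low",
    LowGrayLevelZoneEmphasis = "lgl",
    SizeZoneNonUniformity = "sjn",
    SizeZoneNonUniformityNormalized = "sjnn",
    SmallAreaEmphasis = "small",
    SmallAreaHighGrayLevelEmphasis = "small_high",
    SmallAreaLowGrayLevelEmphasis = "small_low",
    ZoneEntropy = "entropy",
    ZonePercentage = "pct",
    ZoneVariance = "jv"))
}

#' GLDM dependence features
#'
#' The 14 dependence features. The dependence size of a voxel is 1 (itself)
#' plus the number of 26-neighbors whose gray level differs by at most
#' `alpha`.
#'
#' @param roi a `discretized_roi` (or integer level array).
#' @param alpha maximum absolute level difference for a neighbor to count as
#'   dependent; 0 is the study default.
#' @return named numeric feature vector.
#' @export
gldm_features <- function(roi, alpha = 0L) {
  roi <- as_discretized(roi)
  counts <- gldm_matrix(roi, alpha)
  level_size_features(counts, roi$voxel_count, c(
    DependenceEntropy = "entropy",
    DependenceNonUniformity = "sjn",
    DependenceNonUniformityNormalized = "sjnn",
    DependenceVariance = "jv",
    GrayLevelNonUniformity = "gln",
    GrayLevelVariance = "glv",
    HighGrayLevelEmphasis = "hgl",
    LargeDependenceEmphasis = "large",
    LargeDependenceHighGrayLevelEmphasis = "large_high",
    LargeDependenceLowGrayLevelEmphasis = "large_low",
    LowGrayLevelEmphasis = "lgl",
    SmallDependenceEmphasis = "small",
    SmallDependenceHighGrayLevelEmphasis = "small_high",
    SmallDependenceLowGrayLevelEmphasis = "small_low"))
}

# Feature vector of one ROI cube: per-ROI Min-Max normalization, equal-width
# discretization, then all five families with family-prefixed names.
extract_roi_features <- function(vox, n_levels = 25L, distance = 1L,
                                 alpha = 0L, voxel_volume = 1) {
  norm <- minmax_normalize(vox)
  lv <- discretize(norm, n_levels)
  fo <- firstorder_features(norm, lv, voxel_volume)
  gl <- glcm_features(glcm(lv, distance))
  rl <- glrlm_features(lv)
  sz <- glszm_features(lv)
  dm <- gldm_features(lv, alpha)
  c(stats::setNames(fo, paste0("firstorder_", names(fo))),
    stats::setNames(gl, paste0("glcm_", names(gl))),
    stats::setNames(rl, paste0("glrlm_", names(rl))),
    stats::setNames(sz, paste0("glszm_", names(sz))),
    stats::setNames(dm, paste0("gldm_", names(dm))))
}

#' Extract all radiomic features from a labeled phantom volume
#'
#' Identifies the labeled ROI cubes (connected components of the non-background
#' label map), and for each cube applies per-ROI Min-Max normalization,
#' equal-width discretization, and the five feature families (first-order,
#' GLCM, GLRLM, GLSZM, GLDM). Column names are family-prefixed.
#'
#' @param volume a `phantom_volume` (see [simulate_phantom()] /
#'   [read_nifti()]).
#' @param n_levels gray levels for discretization (study default 25).
#' @param distance GLCM pair distance (voxels).
#' @param alpha GLDM dependence tolerance.
#' @param batch batch label assigned to every row (a single volume comes from
#'   one scanner).
#' @return a [feature_table()] with one row per labeled cube; the class label
#'   is the cube's label-map code (0 or 1).
#' @export
extract_all <- function(volume, n_levels = 25L, distance = 1L, alpha = 0L,
                        batch = "scanner1") {
  stopifnot(inherits(volume, "phantom_volume"))
  lab <- volume$label_map
  if (!any(lab >= 0L)) stop("input error: label map contains no ROI")
  mask <- array(0L, dim = dim(lab))
  mask[lab >= 0L] <- 1L
  comp <- label_components(mask, neighbor_offsets_26(), by_level = FALSE)
  ncube <- max(comp)
  voxel_volume <- prod(volume$voxel_spacing)
  rows <- vector("list", ncube)
  cls <- integer(ncube)
  for (k in seq_len(ncube)) {
    idx <- which(comp == k)
    ai <- arrayInd(idx, dim(lab))
    rng <- apply(ai, 2, range)
    vox <- volume$voxels[rng[1, 1]:rng[2, 1],
                         rng[1, 2]:rng[2, 2],
                         rng[1, 3]:rng[2, 3], drop = FALSE]
    sub <- comp[rng[1, 1]:rng[2, 1], rng[1, 2]:rng[2, 2],
                rng[1, 3]:rng[2, 3], drop = FALSE]
    vox[sub != k] <- NA
    rows[[k]] <- extract_roi_features(vox, n_levels, distance, alpha,
                                      voxel_volume)
    cls[k] <- lab[idx[1]]
  }
  values <- do.call(rbind, rows)
  feature_table(values, batch = rep(batch, ncube), class = cls,
                sample_id = sprintf("cube%03d", seq_len(ncube)))
}
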