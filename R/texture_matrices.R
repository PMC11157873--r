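# Gray-level preprocessing and texture-matrix builders (GLCM, GLRLM, GLSZM,
# GLDM). Matrices follow the IBSI-style definitions used by standard
# radiomics extractors; 1D/2D inputs are treated as degenerate 3D arrays so
# the same builders serve tiny hand-checkable fixtures and real ROI cubes.

as_array3d <- function(x) {
  if (is.null(dim(x))) dim(x) <- c(length(x), 1L, 1L)
  if (length(dim(x)) == 2) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) != 3) stop("input must be at most 3-dimensional")
  x
}

# The 13 unique 3D directions: one representative per +/- pair of the 26
# neighbor offsets (first nonzero component positive).
unique_directions_3d <- function() {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  keep <- apply(g, 1, function(v) {
    nz <- v[v != 0]
    nz[1] > 0
  })
  as.matrix(g[keep, , drop = FALSE])
}

# All 26 neighbor offsets (Chebyshev distance 1).
neighbor_offsets_26 <- function() {
  d <- unique_directions_3d()
  rbind(d, -d)
}

#' Min-Max normalize ROI voxel values to [0, 1]
#'
#' Linearly maps the ROI to `[0, 1]` via `(x - min) / (max - min)`. A
#' constant ROI maps to all zeros (documented degenerate convention). `NA`
#' entries (background) are preserved.
#'
#' @param roi_voxels numeric vector or array of in-ROI voxel values.
#' @return object of the same shape with in-ROI values in `[0, 1]`.
#' @export
minmax_normalize <- function(roi_voxels) {
  v <- roi_voxels[!is.na(roi_voxels)]
  if (length(v) == 0) stop("input error: empty ROI")
  lo <- min(v); hi <- max(v)
  if (hi == lo) {
    out <- roi_voxels
    out[!is.na(out)] <- 0
    return(out)
  }
  (roi_voxels - lo) / (hi - lo)
}

#' Discretize normalized voxel values into gray levels
#'
#' Equal-width binning of `[0, 1]` into `n_levels` bins; the value 1.0 is
#' assigned to the top level. `NA` entries are background and receive level 0.
#'
#' @param roi_voxels numeric values in `[0, 1]` (vector or array).
#' @param n_levels number of gray levels (>= 2); 25 is the study default.
#' @return a list of class `"discretized_roi"` with `levels` (3D integer
#'   array, 0 = background), `n_levels` and `voxel_count`.
#' @export
discretize <- function(roi_voxels, n_levels = 25L) {
  n_levels <- as.integer(n_levels)
  if (n_levels < 2) stop("configuration error: 'n_levels' must be >= 2")
  x <- as_array3d(roi_voxels)
  inroi <- !is.na(x)
  if (!any(inroi)) stop("input error: empty ROI")
  v <- x[inroi]
  if (any(v < -1e-12 | v > 1 + 1e-12)) {
    stop("input error: values must lie in [0, 1]; run minmax_normalize first")
  }
  lv <- array(0L, dim = dim(x))
  lv[inroi] <- pmin.int(floor(pmin(pmax(v, 0), 1) * n_levels) + 1L, n_levels)
  structure(list(levels = lv, n_levels = n_levels,
                 voxel_count = sum(inroi)),
            class = "discretized_roi")
}

as_discretized <- function(roi) {
  if (inherits(roi, "discretized_roi")) return(roi)
  lv <- as_array3d(roi)
  storage.mode(lv) <- "integer"
  if (any(lv < 0L, na.rm = TRUE)) stop("levels must be >= 0")
  lv[is.na(lv)] <- 0L
  structure(list(levels = lv, n_levels = max(lv, 1L),
                 voxel_count = sum(lv > 0L)),
            class = "discretized_roi")
}

new_texture_matrix <- function(kind, m, normalized) {
  structure(list(kind = kind, matrix = m, normalized = normalized),
            class = "texture_matrix")
}

#' Gray-level co-occurrence matrix of a discretized ROI
#'
#' Counts symmetric pairs of in-ROI voxel levels separated by `distance`
#' along each direction; counts are pooled over the 13 unique 3D directions
#' (single aggregated matrix) and normalized to sum to one.
#'
#' @param roi a `discretized_roi` (or integer level array, 0 = background).
#' @param distance pair offset length in voxels along each direction axis.
#' @param directions optional integer matrix of direction triples (one row
#'   each); defaults to the 13 unique 3D directions.
#' @param normalize divide by the total pair count (default `TRUE`).
#' @return a `texture_matrix` of kind `"GLCM"`, square
#'   `n_levels x n_levels` and symmetric.
#' @export
glcm <- function(roi, distance = 1L, directions = NULL, normalize = TRUE) {
  roi <- as_discretized(roi)
  if (is.null(directions)) directions <- unique_directions_3d()
  directions <- as.matrix(directions)
  lv <- roi$levels
  ng <- roi$n_levels
  d <- dim(lv)
  counts <- matrix(0, ng, ng)
  for (k in seq_len(nrow(directions))) {
    off <- directions[k, ] * as.integer(distance)
    lo <- pmax(1L, 1L - off)
    hi <- pmin(d, d - off)
    if (any(lo > hi)) next
    rx <- lo[1]:hi[1]; ry <- lo[2]:hi[2]; rz <- lo[3]:hi[3]
    a <- lv[rx, ry, rz, drop = FALSE]
    b <- lv[rx + off[1], ry + off[2], rz + off[3], drop = FALSE]
    keep <- a > 0L & b > 0L
    if (!any(keep)) next
    idx <- (a[keep] - 1L) * ng + b[keep]
    tab <- tabulate(idx, nbins = ng * ng)
    counts <- counts + matrix(tab, ng, ng, byrow = TRUE)
  }
  counts <- counts + t(counts)     # symmetric pairing
  total <- sum(counts)
  if (total == 0) {
    stop("degenerate-matrix error: no voxel pairs at the requested distance")
  }
  if (normalize) counts <- counts / total
  new_texture_matrix("GLCM", counts, normalize)
}

# Run-length matrix: P[level, run length], runs pooled over the given
# directions (default: all 13 unique 3D directions).
glrlm_matrix <- function(roi, directions = NULL) {
  roi <- as_discretized(roi)
  if (is.null(directions)) directions <- unique_directions_3d()
  directions <- as.matrix(directions)
  lv <- roi$levels
  d <- dim(lv)
  ng <- roi$n_levels
  maxlen <- max(d)
  counts <- matrix(0, ng, maxlen)
  for (k in seq_len(nrow(directions))) {
    off <- directions[k, ]
    # line starts: voxels whose predecessor along -off is out of bounds
    coords <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                          z = seq_len(d[3]))
    px <- coords$x - off[1]; py <- coords$y - off[2]; pz <- coords$z - off[3]
    is_start <- px < 1 | px > d[1] | py < 1 | py > d[2] | pz < 1 | pz > d[3]
    starts <- coords[is_start, , drop = FALSE]
    for (s in seq_len(nrow(starts))) {
      # gather the whole line in one vectorized stride
      tmax_comp <- function(pos, step, lim) {
        if (step > 0) (lim - pos) %/% step
        else if (step < 0) (pos - 1) %/% (-step)
        else .Machine$integer.max
      }
      tmax <- min(tmax_comp(starts$x[s], off[1], d[1]),
                  tmax_comp(starts$y[s], off[2], d[2]),
                  tmax_comp(starts$z[s], off[3], d[3]))
      t <- 0:tmax
      ix <- starts$x[s] + t * off[1]
      iy <- starts$y[s] + t * off[2]
      iz <- starts$z[s] + t * off[3]
      line <- lv[cbind(ix, iy, iz)]
      r <- rle(line)
      keep <- r$values > 0L
      if (any(keep)) {
        ij <- cbind(r$values[keep], r$lengths[keep])
        for (q in seq_len(nrow(ij))) {
          counts[ij[q, 1], ij[q, 2]] <- counts[ij[q, 1], ij[q, 2]] + 1
        }
      }
    }
  }
  counts
}

# Connected-component labeling on a 3D integer level array. Components are
# maximal sets of in-ROI (level > 0) voxels connected through the given
# offsets; when by_level, members must share the same level (GLSZM zones).
label_components <- function(levels, offsets, by_level = TRUE) {
  d <- dim(levels)
  comp <- array(0L, dim = d)
  unvisited <- levels > 0L
  k <- 0L
  while (any(unvisited)) {
    seed <- which(unvisited)[1]
    sc <- arrayInd(seed, d)
    k <- k + 1L
    val <- levels[seed]
    frontier <- sc
    comp[seed] <- k
    unvisited[seed] <- FALSE
    while (nrow(frontier) > 0) {
      cand <- do.call(rbind, lapply(seq_len(nrow(offsets)), function(o) {
        sweep(frontier, 2, offsets[o, ], "+")
      }))
      ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
        cand[, 2] >= 1 & cand[, 2] <= d[2] &
        cand[, 3] >= 1 & cand[, 3] <= d[3]
      cand <- cand[ok, , drop = FALSE]
      if (nrow(cand) == 0) break
      lin <- cand[, 1] + (cand[, 2] - 1L) * d[1] + (cand[, 3] - 1L) * d[1] * d[2]
      keep <- unvisited[lin] & (if (by_level) levels[lin] == val else TRUE)
      lin <- unique(lin[keep])
      if (length(lin) == 0) break
      comp[lin] <- k
      unvisited[lin] <- FALSE
      frontier <- arrayInd(lin, d)
    }
  }
  comp
}

# Size-zone matrix: P[level, zone size]; zones are 26-connected components
# of equal level.
glszm_matrix <- function(roi) {
  roi <- as_discretized(roi)
  comp <- label_components(roi$levels, neighbor_offsets_26(), by_level = TRUE)
  ids <- which(comp > 0L)
  if (length(ids) == 0) stop("input error: empty ROI")
  zone_id <- comp[ids]
  zone_level <- tapply(roi$levels[ids], zone_id, function(v) v[1])
  zone_size <- tabulate(zone_id)
  ng <- roi$n_levels
  counts <- matrix(0, ng, max(zone_size))
  for (z in seq_along(zone_size)) {
    counts[zone_level[z], zone_size[z]] <- counts[zone_level[z], zone_size[z]] + 1
  }
  counts
}

# Dependence matrix: P[level, dependence size]; dependence size of a voxel is
# 1 (itself) plus the number of 26-neighbors whose level differs by <= alpha.
gldm_matrix <- function(roi, alpha = 0L) {
  roi <- as_discretized(roi)
  lv <- roi$levels
  d <- dim(lv)
  dep <- array(1L, dim = d)         # the voxel depends on itself
  offs <- neighbor_offsets_26()
  for (k in seq_len(nrow(offs))) {
    off <- offs[k, ]
    lo <- pmax(1L, 1L - off)
    hi <- pmin(d, d - off)
    if (any(lo > hi)) next
    rx <- lo[1]:hi[1]; ry <- lo[2]:hi[2]; rz <- lo[3]:hi[3]
    a <- lv[rx, ry, rz, drop = FALSE]
    b <- lv[rx + off[1], ry + off[2], rz + off[3], drop = FALSE]
    inc <- (a > 0L) & (b > 0L) & (abs(a - b) <= alpha)
    dep[rx, ry, rz] <- dep[rx, ry, rz, drop = FALSE] + inc
  }
  inroi <- lv > 0L
  ng <- roi$n_levels
  maxdep <- max(dep[inroi])
  counts <- matrix(0, ng, maxdep)
  idx <- (lv[inroi] - 1L) * maxdep + dep[inroi]
  tab <- tabulate(idx, nbins = ng * maxdep)
  counts <- matrix(tab, ng, maxdep, byrow = TRUE)
  counts
}
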