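#' Simulation configuration for multi-scanner radiomic feature tables
#'
#' The generator follows the location/scale batch-effect model under which
#' harmonization is derived: the value of feature \eqn{g} for sample \eqn{j}
#' on scanner batch \eqn{i} is
#' \deqn{y_{ijg} = \alpha_g + X \beta_g + \gamma_{ig} + \delta_{ig}\,\epsilon_{ijg},}
#' where \eqn{X} is the binary class indicator, \eqn{\gamma_{ig}} the additive
#' and \eqn{\delta_{ig}} the multiplicative scanner effect, and
#' \eqn{\epsilon_{ijg} \sim N(0, \mathrm{noise\_sd}^2)} i.i.d.
#'
#' Ground-truth parameter distributions match the prior families the
#' empirical-Bayes step assumes, so parameter-recovery tests are meaningful:
#' \eqn{\alpha_g \sim N(0,1)}, \eqn{\beta_g \sim N(0, \mathrm{class\_effect\_scale}^2)},
#' \eqn{\gamma_{ig} \sim N(0, \mathrm{additive\_effect\_scale}^2)},
#' \eqn{\delta_{ig} \sim U(\mathrm{multiplicative\_effect\_range})}.
#'
#' @param n_per_batch integer vector of samples per scanner batch; at least 2
#'   batches with at least 2 samples each. Default `c(53, 42, 40)`, the
#'   retained Siemens/Philips/GE cohort sizes of the phantom study design the
#'   generator emulates.
#' @param n_features number of radiomic features to simulate.
#' @param class_effect_scale standard deviation of the per-feature class
#'   effect \eqn{\beta_g} (0 = no class signal).
#' @param additive_effect_scale standard deviation of the additive batch
#'   effects \eqn{\gamma_{ig}} (0 = no additive batch effect).
#' @param multiplicative_effect_range length-2 positive vector `(lo, hi)`
#'   bounding the multiplicative batch effects \eqn{\delta_{ig}};
#'   `c(1, 1)` disables them.
#' @param noise_sd standard deviation of the within-batch noise.
#' @param seed integer seed; the single source of randomness for a run.
#'
#' @return a validated list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_per_batch = c(53L, 42L, 40L),
                              n_features = 100L,
                              class_effect_scale = 1,
                              additive_effect_scale = 1.5,
                              multiplicative_effect_range = c(0.5, 2),
                              noise_sd = 1,
                              seed = 1L) {
  n_per_batch <- as.integer(n_per_batch)
  if (length(n_per_batch) < 2) {
    stop("configuration error in 'n_per_batch': at least 2 batches required")
  }
  if (any(n_per_batch < 2)) {
    stop("configuration error in 'n_per_batch': every batch needs >= 2 samples")
  }
  if (length(n_features) != 1 || n_features < 1) {
    stop("configuration error in 'n_features': must be a positive integer")
  }
  if (class_effect_scale < 0) {
    stop("configuration error in 'class_effect_scale': must be nonnegative")
  }
  if (additive_effect_scale < 0) {
    stop("configuration error in 'additive_effect_scale': must be nonnegative")
  }
  r <- multiplicative_effect_range
  if (length(r) != 2 || r[1] <= 0 || r[2] < r[1]) {
    stop("configuration error in 'multiplicative_effect_range': ",
         "need 0 < lo <= hi")
  }
  if (noise_sd <= 0) {
    stop("configuration error in 'noise_sd': must be positive")
  }
  structure(list(n_per_batch = n_per_batch,
                 n_features = as.integer(n_features),
                 class_effect_scale = class_effect_scale,
                 additive_effect_scale = additive_effect_scale,
                 multiplicative_effect_range = as.numeric(r),
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a multi-scanner radiomic feature table with known ground truth
#'
#' Draws ground-truth parameters and noise from the generative model described
#' in [simulation_config()] and assembles a [feature_table()]. Classes are
#' balanced within every batch (alternating 0/1), mirroring a paired phantom
#' design with one ROI per cartridge texture per cohort.
#'
#' @param config a [simulation_config()].
#' @return a list with elements `table` (a `feature_table`) and `truth`
#'   (list with `alpha`, `beta` per feature; `gamma`, `delta` batch-by-feature
#'   matrices).
#' @export
simulate_features <- function(config) {
  if (!inherits(config, "simulation_config")) {
    config <- do.call(simulation_config, config)
  }
  nb <- length(config$n_per_batch)
  G <- config$n_features
  n <- sum(config$n_per_batch)
  batch_names <- sprintf("scanner%d", seq_len(nb))
  withr::with_seed(config$seed, {
    alpha <- stats::rnorm(G)
    beta <- if (config$class_effect_scale > 0) {
      stats::rnorm(G, 0, config$class_effect_scale)
    } else rep(0, G)
    gamma <- if (config$additive_effect_scale > 0) {
      matrix(stats::rnorm(nb * G, 0, config$additive_effect_scale), nb, G)
    } else matrix(0, nb, G)
    r <- config$multiplicative_effect_range
    delta <- if (r[1] == r[2]) {
      matrix(r[1], nb, G)
    } else matrix(stats::runif(nb * G, r[1], r[2]), nb, G)
    eps <- matrix(stats::rnorm(n * G, 0, config$noise_sd), n, G)
  })
  dimnames(gamma) <- dimnames(delta) <- list(batch_names, NULL)

  batch <- rep(batch_names, times = config$n_per_batch)
  # alternating class labels within each batch -> balanced paired design
  cls <- unlist(lapply(config$n_per_batch,
                       function(m) rep_len(c(0L, 1L), m)), use.names = FALSE)
  bi <- rep(seq_len(nb), times = config$n_per_batch)
  values <- matrix(alpha, n, G, byrow = TRUE) +
    outer(cls, beta) +
    gamma[bi, , drop = FALSE] +
    delta[bi, , drop = FALSE] * eps
  tbl <- feature_table(values, batch = batch, class = cls)
  list(table = tbl,
       truth = list(alpha = alpha, beta = beta, gamma = gamma, delta = delta))
}

#' Default texture descriptors for the synthetic two-cartridge phantom
#'
#' Class 0 emulates a rubber-particle cartridge: high-frequency speckle, i.e.
#' white noise smoothed with a one-voxel box kernel. Class 1 emulates a
#' honeycomb-filled ABS cartridge: a thresholded sum of three phase-shifted
#' sinusoids plus noise, giving a periodic two-intensity pattern.
#'
#' @param speckle_sd noise sd of the class-0 speckle before smoothing.
#' @param honeycomb_period period (voxels) of the class-1 sinusoids.
#' @param honeycomb_contrast intensity separation of the two class-1 phases.
#' @param honeycomb_noise_sd additive noise sd on the class-1 pattern.
#' @return list of per-class texture descriptors.
#' @export
phantom_textures <- function(speckle_sd = 1, honeycomb_period = 4,
                             honeycomb_contrast = 2, honeycomb_noise_sd = 0.25) {
  list(speckle_sd = speckle_sd,
       honeycomb_period = honeycomb_period,
       honeycomb_contrast = honeycomb_contrast,
       honeycomb_noise_sd = honeycomb_noise_sd)
}

# 3x3x3 box smoothing with edge replication; cheap separable mean filter.
smooth_box3 <- function(a) {
  sm_axis <- function(x, axis) {
    d <- dim(x)
    idx_lo <- pmax(seq_len(d[axis]) - 1L, 1L)
    idx_hi <- pmin(seq_len(d[axis]) + 1L, d[axis])
    pick <- function(i) switch(axis,
                               x[i, , , drop = FALSE],
                               x[, i, , drop = FALSE],
                               x[, , i, drop = FALSE])
    (pick(idx_lo) + pick(seq_len(d[axis])) + pick(idx_hi)) / 3
  }
  sm_axis(sm_axis(sm_axis(a, 1L), 2L), 3L)
}

#' Simulate a labeled two-texture phantom volume
#'
#' Packs `2 * n_cubes_per_class` non-overlapping cubes of side `side_voxels`
#' into a 3D volume on a regular grid with one-voxel gaps, filling class-0
#' cubes with speckle texture and class-1 cubes with a periodic honeycomb-like
#' pattern (see [phantom_textures()]), so the two classes are separable by
#' texture features. The label map codes background as -1 and labeled cubes as
#' their class (0 or 1).
#'
#' @param side_voxels side length of each ROI cube (>= 5), identical for all
#'   cubes.
#' @param n_cubes_per_class number of cubes per texture class.
#' @param texture_params per-class texture descriptors, see [phantom_textures()].
#' @param seed integer seed.
#' @param volume_dim optional integer triple fixing the volume dimensions; an
#'   error is raised when the cubes cannot be packed into it. By default the
#'   volume is sized to fit the cube grid exactly.
#' @param voxel_spacing voxel size in mm, default `c(1, 1, 1)`.
#' @return a list of class `"phantom_volume"` with `voxels` (3D numeric
#'   array), `label_map` (3D integer array, -1 background / 0 rubber /
#'   1 ABS-like), and `voxel_spacing`.
#' @export
simulate_phantom <- function(side_voxels, n_cubes_per_class,
                             texture_params = phantom_textures(),
                             seed = 1L, volume_dim = NULL,
                             voxel_spacing = c(1, 1, 1)) {
  side_voxels <- as.integer(side_voxels)
  if (side_voxels < 5) stop("'side_voxels' must be at least 5")
  if (n_cubes_per_class < 1) stop("'n_cubes_per_class' must be positive")
  n_cubes <- 2L * as.integer(n_cubes_per_class)
  # grid of cube slots: smallest box of slots holding n_cubes
  kx <- ceiling(n_cubes^(1 / 3))
  ky <- ceiling(sqrt(n_cubes / kx))
  kz <- ceiling(n_cubes / (kx * ky))
  grid <- c(kx, ky, kz)
  pitch <- side_voxels + 1L       # one-voxel gap between cubes
  need <- grid * pitch + 1L
  if (is.null(volume_dim)) {
    volume_dim <- need
  } else {
    volume_dim <- as.integer(volume_dim)
    if (length(volume_dim) != 3 || any(volume_dim < need)) {
      stop(sprintf(paste0("sizing error: %d cubes of side %d need a volume ",
                          "of at least %s"),
                   n_cubes, side_voxels, paste(need, collapse = "x")))
    }
  }
  voxels <- array(0, dim = volume_dim)
  label_map <- array(-1L, dim = volume_dim)
  tp <- texture_params

  withr::with_seed(seed, {
    cube_class <- rep_len(c(0L, 1L), n_cubes)
    slot <- 0L
    for (iz in seq_len(grid[3])) for (iy in seq_len(grid[2])) {
      for (ix in seq_len(grid[1])) {
        slot <- slot + 1L
        if (slot > n_cubes) break
        ox <- (ix - 1L) * pitch + 2L
        oy <- (iy - 1L) * pitch + 2L
        oz <- (iz - 1L) * pitch + 2L
        rx <- ox:(ox + side_voxels - 1L)
        ry <- oy:(oy + side_voxels - 1L)
        rz <- oz:(oz + side_voxels - 1L)
        cls <- cube_class[slot]
        if (cls == 0L) {
          noise <- array(stats::rnorm(side_voxels^3, 0, tp$speckle_sd),
                         dim = rep(side_voxels, 3))
          cube <- smooth_box3(noise)
        } else {
          ph <- stats::runif(3, 0, 2 * pi)
          w <- 2 * pi / tp$honeycomb_period
          g <- seq_len(side_voxels)
          s <- outer(outer(sin(w * g + ph[1]), sin(w * g + ph[2]), "+"),
                     sin(w * g + ph[3]), "+")
          cube <- ifelse(s > 0, tp$honeycomb_contrast / 2,
                         -tp$honeycomb_contrast / 2) +
            array(stats::rnorm(side_voxels^3, 0, tp$honeycomb_noise_sd),
                  dim = rep(side_voxels, 3))
        }
        voxels[rx, ry, rz] <- cube
        label_map[rx, ry, rz] <- cls
      }
    }
  })
  structure(list(voxels = voxels,
                 label_map = label_map,
                 voxel_spacing = as.numeric(voxel_spacing)),
            class = "phantom_volume")
}

#' @export
print.phantom_volume <- function(x, ...) {
  cat(sprintf("<phantom_volume> %s voxels, %d labeled (%d class-0, %d class-1)\n",
              paste(dim(x$voxels), collapse = "x"),
              sum(x$label_map >= 0L),
              sum(x$label_map == 0L), sum(x$label_map == 1L)))
  invisible(x)
}

#' Write a phantom volume as a NIfTI image/label pair
#'
#' The voxel image and the label map are written as two NIfTI-1 files with
#' identical geometry; `voxel_spacing` is stored in the header pixdim.
#'
#' @param volume a `phantom_volume`.
#' @param image_path path for the voxel image (`.nii` or `.nii.gz`).
#' @param label_path path for the label map.
#' @export
write_nifti <- function(volume, image_path, label_path) {
  stopifnot(inherits(volume, "phantom_volume"))
  img <- RNifti::asNifti(volume$voxels, pixdim = volume$voxel_spacing)
  lab <- RNifti::asNifti(array(as.integer(volume$label_map),
                               dim = dim(volume$label_map)),
                         pixdim = volume$voxel_spacing)
  RNifti::writeNifti(img, image_path)
  RNifti::writeNifti(lab, label_path, datatype = "int16")
  invisible(c(image = image_path, label = label_path))
}

#' Read a phantom volume from a NIfTI image/label pair
#' @param image_path NIfTI voxel image path.
#' @param label_path NIfTI label map path; must share the image geometry.
#' @return a `phantom_volume`.
#' @export
read_nifti <- function(image_path, label_path) {
  img <- tryCatch(RNifti::readNifti(image_path),
                  error = function(e) stop("format error reading '",
                                           image_path, "': ",
                                           conditionMessage(e), call. = FALSE))
  lab <- tryCatch(RNifti::readNifti(label_path),
                  error = function(e) stop("format error reading '",
                                           label_path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (!identical(dim(img)[1:3], dim(lab)[1:3])) {
    stop("format error: image and label map dimensions differ")
  }
  spacing <- RNifti::pixdim(img)[1:3]
  structure(list(voxels = array(as.numeric(img), dim = dim(img)[1:3]),
                 label_map = array(as.integer(round(as.numeric(lab))),
                                   dim = dim(lab)[1:3]),
                 voxel_spacing = as.numeric(spacing)),
            class = "phantom_volume")
}
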