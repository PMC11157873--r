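test_that("min-max normalization maps ROIs to [0,1] with stated conventions", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(minmax_normalize(c(5, 5)), c(0, 0))
  expect_error(minmax_normalize(c(NA_real_, NA_real_)), "empty ROI")
  set.seed(1)
  x <- rnorm(50)
  nx <- minmax_normalize(x)
  expect_equal(range(nx), c(0, 1))
})

test_that("discretization uses equal-width bins with the top edge closed", {
  d <- discretize(c(0, 0.5, 1), n_levels = 2)
  expect_equal(as.vector(d$levels), c(1L, 2L, 2L))
  expect_error(discretize(c(0, 1), n_levels = 1), "configuration error")
  d25 <- discretize(seq(0, 1, length.out = 100), n_levels = 25)
  expect_lte(max(d25$levels), 25L)
  expect_equal(d25$voxel_count, 100L)
  d0 <- discretize(rep(0, 10), n_levels = 4)
  expect_true(all(d0$levels == 1L))
})

test_that("GLCM matches hand-enumerated pairs and is symmetric", {
  lv <- matrix(c(1L, 1L, 2L, 2L), 2, 2, byrow = TRUE)  # rows: 1 1 / 2 2
  m <- glcm(lv, directions = matrix(c(0, 1, 0), 1))    # within-row neighbor
  expect_equal(m$matrix, matrix(c(0.5, 0, 0, 0.5), 2, 2))
  # symmetry over all 13 directions on a random array
  set.seed(4)
  arr <- array(sample(1:4, 4 * 4 * 3, replace = TRUE), dim = c(4, 4, 3))
  full <- glcm(arr)
  expect_equal(full$matrix, t(full$matrix))
  expect_equal(sum(full$matrix), 1)
})

test_that("matrix builders agree exactly with brute-force enumeration", {
  set.seed(11)
  for (rep in 1:5) {
    lv <- array(sample(0:3, 16, replace = TRUE, prob = c(0.1, 0.3, 0.3, 0.3)),
                dim = c(4, 4, 1))
    if (max(lv) == 0) next
    impl <- glcm(lv, normalize = FALSE)$matrix
    expect_equal(impl, oracle_glcm(lv), ignore_attr = TRUE)
    expect_equal(radcombat:::glrlm_matrix(radcombat:::as_discretized(lv)),
                 cbind(oracle_glrlm(lv),
                       matrix(0, max(lv), 4 - ncol(oracle_glrlm(lv)))),
                 ignore_attr = TRUE)
    zm <- radcombat:::glszm_matrix(radcombat:::as_discretized(lv))
    zo <- oracle_glszm(lv)
    expect_equal(zm[, seq_len(ncol(zo)), drop = FALSE], zo,
                 ignore_attr = TRUE)
    expect_true(all(zm[, -seq_len(ncol(zo))] == 0))
    dm <- radcombat:::gldm_matrix(radcombat:::as_discretized(lv), 0L)
    do_ <- oracle_gldm(lv, 0)
    expect_equal(dm[, seq_len(ncol(do_)), drop = FALSE], do_,
                 ignore_attr = TRUE)
  }
})

test_that("constant-ROI conventions hold across families", {
  const <- array(1L, dim = c(3, 3, 3))
  g <- glcm_features(glcm(const))
  expect_equal(unname(g["Contrast"]), 0)
  expect_equal(unname(g["JointEnergy"]), 1)
  expect_equal(unname(g["Correlation"]), 1)   # zero-variance convention
  z <- radcombat:::glszm_matrix(radcombat:::as_discretized(const))
  expect_equal(sum(z), 1)                     # one zone ...
  expect_equal(z[1, 27], 1)                   # ... of size 27
  fo <- firstorder_features(rep(0.5, 27), discretize(rep(0.5, 27), 4))
  expect_equal(unname(fo["Variance"]), 0)
  expect_equal(unname(fo["Skewness"]), 0)
})

test_that("first-order features match direct computation", {
  x <- c(0, 0.5, 1)
  fo <- firstorder_features(x, discretize(x, 2))
  expect_equal(unname(fo["Mean"]), 0.5)
  expect_equal(unname(fo["Range"]), 1)
  expect_equal(unname(fo["RootMeanSquared"]), sqrt(mean(x^2)))
  # Entropy/Uniformity from the 2-level histogram (1/3, 2/3)
  p <- c(1 / 3, 2 / 3)
  expect_equal(unname(fo["Entropy"]), -sum(p * log2(p)))
  expect_equal(unname(fo["Uniformity"]), sum(p^2))
})

test_that("run enumeration on a 1D strip matches the brute-force oracle", {
  lv <- array(c(1L, 1L, 1L, 2L), dim = c(4, 1, 1))
  m <- radcombat:::glrlm_matrix(radcombat:::as_discretized(lv),
                                directions = matrix(c(1, 0, 0), 1))
  expect_equal(m[1, 3], 1)   # run of level 1, length 3
  expect_equal(m[2, 1], 1)   # run of level 2, length 1
  expect_equal(sum(m), 2)
  f <- glrlm_features(lv, directions = matrix(c(1, 0, 0), 1))
  # Run Length non uniformity by hand: (1 run of len 3)^2 + (1 of len 1)^2 / 2
  expect_equal(unname(f["RunLengthNonUniformity"]), (1^2 + 1^2) / 2)
  expect_equal(unname(f["LongRunEmphasis"]), (9 + 1) / 2)
})

test_that("extraction yields one translation-invariant row per cube", {
  vol <- simulate_phantom(side_voxels = 6, n_cubes_per_class = 1, seed = 21)
  ft <- extract_all(vol)
  expect_equal(nrow(ft), 2)
  expect_equal(length(feature_names(ft)), 86)
  expect_equal(sort(unique(ft$class)), c(0L, 1L))
  # translation invariance: duplicate one cube at another position
  side <- 5L
  v <- array(0, dim = c(18, 12, 12))
  l <- array(-1L, dim = c(18, 12, 12))
  set.seed(5)
  cube <- array(rnorm(side^3), dim = rep(side, 3))
  v[2:6, 2:6, 2:6] <- cube;    l[2:6, 2:6, 2:6] <- 0L
  v[12:16, 5:9, 4:8] <- cube;  l[12:16, 5:9, 4:8] <- 1L
  vol2 <- structure(list(voxels = v, label_map = l,
                         voxel_spacing = c(1, 1, 1)),
                    class = "phantom_volume")
  ft2 <- extract_all(vol2)
  expect_equal(unname(feature_matrix(ft2)[1, ]),
               unname(feature_matrix(ft2)[2, ]), tolerance = 1e-12)
})

test_that("phantom textures separate the classes with a large effect size", {
  vol <- simulate_phantom(side_voxels = 8, n_cubes_per_class = 4, seed = 31)
  ft <- extract_all(vol)
  fm <- feature_matrix(ft)
  cls <- ft$class
  d <- apply(fm, 2, function(v) {
    s <- sqrt((var(v[cls == 0]) + var(v[cls == 1])) / 2)
    if (s == 0) 0 else (mean(v[cls == 1]) - mean(v[cls == 0])) / s
  })
  expect_gt(max(abs(d)), 1)
})
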