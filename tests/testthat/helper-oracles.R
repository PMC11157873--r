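# Independent brute-force oracles used by the texture and harmonization
# tests. These are deliberately written as plain loops straight from the
# definitions, sharing no code with the package implementations.

# All 26 offsets / 13 unique directions, enumerated longhand.
oracle_offsets26 <- function() {
  out <- list()
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    out[[length(out) + 1]] <- c(dx, dy, dz)
  }
  do.call(rbind, out)
}

oracle_directions13 <- function() {
  offs <- oracle_offsets26()
  keep <- logical(nrow(offs))
  for (r in seq_len(nrow(offs))) {
    v <- offs[r, ]
    nz <- v[v != 0]
    keep[r] <- nz[1] > 0
  }
  offs[keep, , drop = FALSE]
}

in_bounds <- function(p, d) all(p >= 1) && all(p <= d)

# GLCM by direct symmetric pair enumeration (counts, unnormalized).
oracle_glcm <- function(lv, distance = 1, directions = oracle_directions13()) {
  d <- dim(lv)
  ng <- max(lv)
  m <- matrix(0, ng, ng)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (lv[x, y, z] == 0) next
    for (r in seq_len(nrow(directions))) {
      q <- c(x, y, z) + directions[r, ] * distance
      if (!in_bounds(q, d)) next
      lb <- lv[q[1], q[2], q[3]]
      if (lb == 0) next
      la <- lv[x, y, z]
      m[la, lb] <- m[la, lb] + 1
      m[lb, la] <- m[lb, la] + 1
    }
  }
  m
}

# Run-length counts by walking every line voxel by voxel.
oracle_glrlm <- function(lv, directions = oracle_directions13()) {
  d <- dim(lv)
  ng <- max(lv)
  m <- matrix(0, ng, max(d))
  for (r in seq_len(nrow(directions))) {
    dir <- directions[r, ]
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      prev <- c(x, y, z) - dir
      if (in_bounds(prev, d)) next        # not a line start
      # walk the line
      pos <- c(x, y, z)
      run_level <- 0L; run_len <- 0L
      while (in_bounds(pos, d)) {
        l <- lv[pos[1], pos[2], pos[3]]
        if (l == run_level) {
          run_len <- run_len + 1L
        } else {
          if (run_level > 0L) m[run_level, run_len] <- m[run_level, run_len] + 1
          run_level <- l; run_len <- 1L
        }
        pos <- pos + dir
      }
      if (run_level > 0L) m[run_level, run_len] <- m[run_level, run_len] + 1
    }
  }
  m
}

# Size-zone counts by recursive region growing over the 26-neighborhood.
oracle_glszm <- function(lv) {
  d <- dim(lv)
  ng <- max(lv)
  seen <- array(FALSE, dim = d)
  offs <- oracle_offsets26()
  zones <- list()
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (lv[x, y, z] == 0 || seen[x, y, z]) next
    level <- lv[x, y, z]
    stack <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    size <- 0L
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1L
      for (r in seq_len(nrow(offs))) {
        q <- p + offs[r, ]
        if (in_bounds(q, d) && !seen[q[1], q[2], q[3]] &&
            lv[q[1], q[2], q[3]] == level) {
          seen[q[1], q[2], q[3]] <- TRUE
          stack[[length(stack) + 1]] <- q
        }
      }
    }
    zones[[length(zones) + 1]] <- c(level, size)
  }
  maxs <- max(vapply(zones, `[`, numeric(1), 2))
  m <- matrix(0, ng, maxs)
  for (zn in zones) m[zn[1], zn[2]] <- m[zn[1], zn[2]] + 1
  m
}

# Dependence counts: 1 + number of 26-neighbors with |level diff| <= alpha.
oracle_gldm <- function(lv, alpha = 0) {
  d <- dim(lv)
  ng <- max(lv)
  offs <- oracle_offsets26()
  recs <- list()
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    l <- lv[x, y, z]
    if (l == 0) next
    dep <- 1L
    for (r in seq_len(nrow(offs))) {
      q <- c(x, y, z) + offs[r, ]
      if (!in_bounds(q, d)) next
      lb <- lv[q[1], q[2], q[3]]
      if (lb > 0 && abs(l - lb) <= alpha) dep <- dep + 1L
    }
    recs[[length(recs) + 1]] <- c(l, dep)
  }
  maxdep <- max(vapply(recs, `[`, numeric(1), 2))
  m <- matrix(0, ng, maxdep)
  for (rc in recs) m[rc[1], rc[2]] <- m[rc[1], rc[2]] + 1
  m
}

# Independently coded parametric EB ComBat reference: per-feature loops,
# per-feature lm() fits, scalar EB iterations, and the location/scale
# back-transform applied term by term.
oracle_combat <- function(Y, batch, cls, tol = 1e-4, max_iter = 100) {
  batch <- factor(batch)
  levs <- levels(batch)
  I <- length(levs)
  n_i <- as.integer(table(batch))
  n <- nrow(Y); G <- ncol(Y)
  out <- matrix(NA_real_, n, G)
  # least squares per feature
  alpha <- beta <- sigma2 <- numeric(G)
  Z <- matrix(NA_real_, n, G)
  for (g in seq_len(G)) {
    fit <- stats::lm(Y[, g] ~ 0 + batch + cls)
    bm <- stats::coef(fit)[seq_len(I)]
    beta[g] <- stats::coef(fit)[["cls"]]
    alpha[g] <- sum(n_i / n * bm)
    sigma2[g] <- sum(stats::resid(fit)^2) / n
    Z[, g] <- (Y[, g] - alpha[g] - cls * beta[g]) / sqrt(sigma2[g])
  }
  gamma_hat <- matrix(NA_real_, I, G)
  delta2_hat <- matrix(NA_real_, I, G)
  for (i in seq_len(I)) for (g in seq_len(G)) {
    zi <- Z[batch == levs[i], g]
    gamma_hat[i, g] <- mean(zi)
    delta2_hat[i, g] <- stats::var(zi)
  }
  for (i in seq_len(I)) {
    gbar <- mean(gamma_hat[i, ])
    t2 <- stats::var(gamma_hat[i, ])
    m <- mean(delta2_hat[i, ]); s2 <- stats::var(delta2_hat[i, ])
    lambda <- (2 * s2 + m^2) / s2
    theta <- (m * s2 + m^3) / s2
    for (g in seq_len(G)) {
      zi <- Z[batch == levs[i], g]
      gs <- gamma_hat[i, g]; ds <- delta2_hat[i, g]
      for (it in seq_len(max_iter)) {
        gs_new <- (n_i[i] * t2 * gamma_hat[i, g] + ds * gbar) /
          (n_i[i] * t2 + ds)
        ds_new <- (theta + 0.5 * sum((zi - gs_new)^2)) /
          (n_i[i] / 2 + lambda - 1)
        delta_change <- max(abs(gs_new - gs), abs(ds_new - ds))
        gs <- gs_new; ds <- ds_new
        if (delta_change < tol) break
      }
      idx <- which(batch == levs[i])
      out[idx, g] <- sqrt(sigma2[g]) * (Z[idx, g] - gs) / sqrt(ds) +
        alpha[g] + cls[idx] * beta[g]
    }
  }
  out
}

# Small deterministic feature table used across tests.
make_toy_table <- function(n_per_batch = c(20, 16), G = 6, seed = 42,
                           additive = 1, mult = c(0.8, 1.25),
                           class_scale = 1, noise = 1) {
  sim <- simulate_features(simulation_config(
    n_per_batch = n_per_batch, n_features = G,
    class_effect_scale = class_scale, additive_effect_scale = additive,
    multiplicative_effect_range = mult, noise_sd = noise, seed = seed))
  sim
}
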