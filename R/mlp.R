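# Minimal multilayer perceptron for binary classification: ReLU hidden
# layers, sigmoid output, binary cross-entropy, minibatch stochastic gradient
# descent. Written in plain matrix algebra; sized for feature tables of a few
# hundred samples by a few dozen features.

mlp_fit <- function(x, y, hidden = rep(32L, 5L), learning_rate = 0.01,
                    epochs = 200L, batch_size = 32L, seed = 1L) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)))
  sizes <- c(ncol(x), hidden, 1L)
  L <- length(sizes) - 1L
  withr::with_seed(seed, {
    W <- lapply(seq_len(L), function(l) {
      matrix(stats::rnorm(sizes[l] * sizes[l + 1], 0, sqrt(2 / sizes[l])),
             sizes[l], sizes[l + 1])
    })
    b <- lapply(seq_len(L), function(l) rep(0, sizes[l + 1]))
    n <- nrow(x)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1, n)]
        xb <- x[idx, , drop = FALSE]
        yb <- y[idx]
        m <- length(idx)
        # forward
        a <- vector("list", L + 1)
        a[[1]] <- xb
        for (l in seq_len(L)) {
          z <- sweep(a[[l]] %*% W[[l]], 2, b[[l]], "+")
          a[[l + 1]] <- if (l < L) pmax(z, 0) else 1 / (1 + exp(-z))
        }
        # backward (cross-entropy + sigmoid gives output delta p - y)
        delta <- (a[[L + 1]] - yb) / m
        for (l in rev(seq_len(L))) {
          gw <- crossprod(a[[l]], delta)
          gb <- colSums(delta)
          if (l > 1) {
            delta <- (delta %*% t(W[[l]])) * (a[[l]] > 0)
          }
          W[[l]] <- W[[l]] - learning_rate * gw
          b[[l]] <- b[[l]] - learning_rate * gb
        }
      }
    }
  })
  structure(list(W = W, b = b, sizes = sizes), class = "radcombat_mlp")
}

mlp_predict <- function(fit, x) {
  a <- as.matrix(x)
  L <- length(fit$W)
  for (l in seq_len(L)) {
    z <- sweep(a %*% fit$W[[l]], 2, fit$b[[l]], "+")
    a <- if (l < L) pmax(z, 0) else 1 / (1 + exp(-z))
  }
  as.numeric(a)
}
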