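# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: windows are re-summed by explicit loops, runs
# are found by exhaustive scanning, and PLS is re-derived with SIMPLS on
# cross-product matrices rather than NIPALS deflation.

# Brute-force windowed mean: re-sums every window with an explicit loop.
oracle_window_means <- function(raw, window) {
  n <- length(raw)
  half <- (window - 1) %/% 2
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i - half >= 1 && i + half <= n) {
      s <- 0
      for (j in (i - half):(i + half)) s <- s + raw[j]
      out[i] <- s / window
    }
  }
  out
}

# Exhaustive scan for maximal hot runs of length >= k (no rle).
oracle_patches <- function(hot, k) {
  n <- length(hot)
  res <- NULL
  i <- 1
  while (i <= n) {
    if (isTRUE(hot[i])) {
      j <- i
      while (j < n && isTRUE(hot[j + 1])) j <- j + 1
      if (j - i + 1 >= k) res <- rbind(res, c(i, j))
      i <- j + 1
    } else i <- i + 1
  }
  if (is.null(res)) res <- matrix(integer(), 0, 2)
  storage.mode(res) <- "integer"
  unname(res)
}

random_sequence <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# Random bead cluster dense enough for real occlusion.
random_cluster <- function(n, spread = 0.5, radius = 0.235) {
  bead_frame(matrix(rnorm(n * 3, 0, spread), n, 3), radii = radius)
}

# SIMPLS (de Jong 1993) for a single response. It deflates the covariance
# vector against an orthonormal basis of loadings instead of deflating X,
# so it shares no code path with the NIPALS implementation; for univariate
# y its coefficients coincide with PLS1.
oracle_simpls_coef <- function(X, y, k) {
  Xc <- scale(X)
  yc <- scale(y)
  p <- ncol(Xc)
  S <- crossprod(Xc, yc)
  R <- V <- matrix(0, p, k)
  Q <- numeric(k)
  for (a in seq_len(k)) {
    r <- drop(S)
    t <- drop(Xc %*% r)
    nt <- sqrt(sum(t^2))
    t <- t / nt
    r <- r / nt
    pl <- drop(crossprod(Xc, t))
    Q[a] <- drop(crossprod(yc, t))
    v <- pl
    if (a > 1) {
      Vp <- V[, seq_len(a - 1), drop = FALSE]
      v <- v - drop(Vp %*% crossprod(Vp, pl))
    }
    v <- v / sqrt(sum(v^2))
    V[, a] <- v
    S <- S - v * drop(crossprod(v, S))
    R[, a] <- r
  }
  Bs <- drop(R %*% Q)
  beta <- Bs * attr(yc, "scaled:scale") / attr(Xc, "scaled:scale")
  intercept <- attr(yc, "scaled:center") -
    sum(beta * attr(Xc, "scaled:center"))
  list(beta = beta, intercept = intercept)
}
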