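test_that("autoscale centres, scales, round-trips and rejects constants", {
  expect_equal(autoscale(matrix(c(1, 2, 3), 3, 1))$X[, 1], c(-1, 0, 1),
               ignore_attr = TRUE)

  set.seed(4)
  X <- matrix(rnorm(40), 10, 4)
  sc <- autoscale(X, rnorm(10))
  expect_equal(colMeans(sc$X), rep(0, 4), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(apply(sc$X, 2, sd), rep(1, 4), tolerance = 1e-12,
               ignore_attr = TRUE)
  # inverse transform restores the input
  back <- sweep(sweep(sc$X, 2, sc$x_scale, "*"), 2, sc$x_center, "+")
  expect_equal(back, X, tolerance = 1e-12, ignore_attr = TRUE)
  # idempotence on an already-standardized matrix
  expect_equal(autoscale(sc$X)$X, sc$X, tolerance = 1e-12)

  Xz <- cbind(X, bad = 1)
  expect_error(autoscale(Xz), "bad")
})

test_that("PLS reduces to OLS in one dimension and fits exactly at full rank", {
  set.seed(2)
  x <- matrix(rnorm(15), 15, 1)
  y <- 2 + 3 * x[, 1] + rnorm(15)
  m <- fit_pls(x, y, 1)
  expect_equal(m$fitted, unname(fitted(lm(y ~ x[, 1]))), tolerance = 1e-10)

  X <- matrix(rnorm(10 * 4), 10, 4)
  yl <- drop(X %*% c(1, -2, 0.5, 3))
  mf <- fit_pls(X, yl, 4)
  expect_lt(max(abs(mf$fitted - yl)), 1e-8)
  expect_equal(mf$r_squared, 1, tolerance = 1e-10)
  expect_error(fit_pls(X, yl, 5), "rank")
})

test_that("NIPALS coefficients equal the SIMPLS oracle on seeded problems", {
  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(rnorm(12 * 6), 12, 6)
    y <- drop(X %*% rnorm(6)) + rnorm(12, 0, 0.3)
    for (k in c(1, 2, 4)) {
      m <- fit_pls(X, y, k)
      orc <- oracle_simpls_coef(X, y, k)
      expect_equal(unname(m$coefficients), orc$beta, tolerance = 1e-8)
      expect_equal(m$intercept, orc$intercept, tolerance = 1e-8)
    }
    # score orthogonality
    m <- fit_pls(X, y, 4)
    G <- crossprod(m$scores)
    expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
    # training predictions reproduce stored fitted values and R^2
    expect_equal(predict(m, X), m$fitted, tolerance = 1e-10)
  }
})

test_that("VIP has the closed one-component form and recovers the driver", {
  set.seed(6)
  X <- matrix(rnorm(20 * 5), 20, 5)
  y <- drop(X %*% rnorm(5)) + rnorm(20, 0, 0.2)
  m1 <- fit_pls(X, y, 1)
  v1 <- vip(m1)
  w <- m1$W[, 1]
  expected <- sqrt(5) * abs(w) / sqrt(sum(w^2))
  expect_equal(v1$vip[match(names(w), v1$descriptor)], unname(expected),
               tolerance = 1e-10)
  expect_equal(sum(v1$vip^2), 5, tolerance = 1e-8)

  # y driven by exactly one descriptor: that descriptor tops the VIP table
  y1 <- X[, 3]
  mv <- fit_pls(X, y1, 2)
  expect_equal(vip(mv)$descriptor[1], "x3")
  expect_equal(sum(vip(mv)$vip^2), 5, tolerance = 1e-8)
})

test_that("LOO selection equals an independently coded refit loop", {
  set.seed(10)
  X <- matrix(rnorm(14 * 5), 14, 5)
  y <- drop(X %*% c(2, -1, 0, 0, 0)) + rnorm(14, 0, 0.3)
  k_max <- 3
  sel <- loo_select(X, y, k_max)

  # second, independently written loop
  pred <- matrix(NA_real_, 14, k_max)
  for (i in 1:14) {
    fit <- fit_pls(X[-i, ], y[-i], k_max, drop_constant = TRUE)
    for (k in 1:k_max) pred[i, k] <- predict(fit, X[i, , drop = FALSE], k = k)
  }
  rmsep <- sqrt(colMeans((pred - y)^2))
  expect_equal(sel$rmsep_by_components, rmsep, tolerance = 1e-10)
  expect_equal(sel$chosen_k,
               which(rmsep <= min(rmsep) * 1.02)[1])

  # noiseless response on a rank-2 X: RMSEP ~ 0 at the true rank
  # (full-rank X would need rank(X) components for an exact PLS fit)
  Tm <- matrix(rnorm(14 * 2), 14, 2)
  P2 <- matrix(rnorm(5 * 2), 5, 2)
  Xlow <- Tm %*% t(P2)
  yl <- drop(Tm %*% c(1, 2))
  seln <- loo_select(Xlow, yl, 3)
  expect_lt(min(seln$rmsep_by_components), 1e-6)
  expect_equal(seln$chosen_k, 2)

  # MREP guards against zero responses
  y0 <- y; y0[1] <- 0
  expect_error(loo_select(X, y0, 2), "zeros")
  alt <- loo_select(X, y0, 2, mrep_mode = "ratio_of_means")
  expect_true(is.finite(alt$mrep))
})

test_that("pure-noise responses choose one component under parsimony", {
  set.seed(12)
  hits <- 0
  for (r in 1:10) {
    X <- matrix(rnorm(16 * 6), 16, 6)
    y <- rnorm(16)
    hits <- hits + (loo_select(X, y, 4)$chosen_k == 1)
  }
  expect_gte(hits, 8)   # RMSEP is non-improving in k in expectation
})

test_that("repeated splits are reproducible and behave at the limits", {
  set.seed(30)
  Tm <- matrix(rnorm(25 * 3), 25, 3)
  X <- Tm %*% t(matrix(rnorm(6 * 3), 6, 3))      # rank-3 descriptor space
  yl <- drop(Tm %*% c(1, 2, -1))
  r1 <- repeated_split(X, yl, n_reps = 20, k_max = 4, seed = 99)
  expect_gte(r1$split_q2_median, 0.999)           # perfect-model limit
  r2 <- repeated_split(X, yl, n_reps = 20, k_max = 4, seed = 99)
  expect_identical(r1$q2, r2$q2)                  # bitwise reproducible
  expect_identical(r1$chosen_k, r2$chosen_k)
  expect_true(all(r1$q2 <= 1))

  # null response: with p > n PLS overfits and held-out Q2 goes negative
  set.seed(31)
  Xw <- matrix(rnorm(20 * 40), 20, 40)
  ynull <- rnorm(20)
  rn <- repeated_split(Xw, ynull, n_reps = 50, k_max = 3, seed = 7)
  expect_lte(rn$split_q2_median, 0)
})

test_that("latent export reproduces training scores and centering identities", {
  set.seed(14)
  X <- matrix(rnorm(18 * 5), 18, 5)
  colnames(X) <- paste0("d", 1:5)
  y <- drop(X %*% rnorm(5)) + rnorm(18, 0, 0.2)
  m <- fit_pls(X, y, 2)
  le <- latent_export(m, X)
  expect_equal(unname(le$scores), unname(m$scores), tolerance = 1e-10)
  # duplicated compound rows give identical coordinates
  le2 <- latent_export(m, X[c(1, 1), , drop = FALSE])
  expect_equal(le2$scores[1, ], le2$scores[2, ])
  # the mean row maps to the origin
  le0 <- latent_export(m, matrix(colMeans(X), 1, 5,
                                 dimnames = list(NULL, colnames(X))))
  expect_equal(unname(le0$scores[1, ]), c(0, 0), tolerance = 1e-10)
  expect_error(latent_export(m, X[, 1:3]), "missing descriptor")
})

test_that("QSPR tables load with keep-lists and constant-column filtering", {
  set.seed(16)
  X <- matrix(rnorm(6 * 4), 6, 4,
              dimnames = list(NULL, c("mw", "logp", "tpsa", "flat")))
  X[, "flat"] <- 2
  dcsv <- tempfile(fileext = ".csv")
  rcsv <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(compound = paste0("c", 1:6), X), dcsv,
                   row.names = FALSE)
  utils::write.csv(data.frame(compound = paste0("c", 1:6),
                              mean_apr_sasa_nm2 = runif(6, 30, 60)), rcsv,
                   row.names = FALSE)
  expect_message(q <- read_qspr_tables(dcsv, rcsv), "constant")
  expect_equal(colnames(q$X), c("mw", "logp", "tpsa"))
  keep <- tempfile()
  writeLines(c("mw", "logp"), keep)
  q2 <- read_qspr_tables(dcsv, rcsv, keep_list = keep)
  expect_equal(colnames(q2$X), c("mw", "logp"))
  writeLines("nope", keep)
  expect_error(read_qspr_tables(dcsv, rcsv, keep_list = keep), "absent")
})
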