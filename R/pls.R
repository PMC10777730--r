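# Partial-least-squares structure-property modelling: NIPALS PLS1 with
# autoscaling, leave-one-out component selection under a parsimony rule,
# repeated-split median-Q2 robustness, VIP scores and latent-space export.

#' Autoscale a descriptor matrix and response
#'
#' Centres every column to mean 0 and scales to unit variance (sample sd).
#' Heterogeneous physicochemical descriptors live on wildly different
#' scales, so autoscaling is the standard preprocessing before PLS.
#'
#' @param X Numeric matrix (n x p), no missing values.
#' @param y Optional numeric response.
#' @return List with `X`, `y` (scaled), `x_center`, `x_scale`, `y_center`,
#'   `y_scale`.
#' @export
autoscale <- function(X, y = NULL) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("X contains missing values; filter before scaling")
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  zero <- which(scl == 0)
  if (length(zero)) {
    nm <- colnames(X)[zero]
    if (is.null(nm)) nm <- as.character(zero)
    stop("zero-variance column(s): ", paste(nm, collapse = ", "),
         "; remove constant descriptors first")
  }
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  out <- list(X = Xs, x_center = ctr, x_scale = scl)
  if (!is.null(y)) {
    y <- as.numeric(y)
    yc <- mean(y); ys <- stats::sd(y)
    if (ys == 0) stop("response has zero variance")
    out$y <- (y - yc) / ys
    out$y_center <- yc
    out$y_scale <- ys
  }
  out
}

#' Fit a PLS regression model (NIPALS, single response)
#'
#' Classical PLS1: per component the weight vector is the normalized
#' covariance direction `X'y / ||X'y||`, scores are `t = X w`, X and y are
#' deflated by the score's least-squares loadings, and regression
#' coefficients are back-transformed to the original scale. For a single
#' response each NIPALS component converges in one pass, so no inner
#' iteration is needed.
#'
#' @param X Numeric n x p descriptor matrix.
#' @param y Numeric response, length n.
#' @param n_components Number of latent components (<= rank of scaled X).
#' @param drop_constant Silently drop zero-variance columns before scaling
#'   (useful inside resampling loops); default `FALSE`, in which case
#'   constant columns are an error.
#' @return Object of class `"pls_model"`: weights `W` (p x k, unit norm),
#'   X loadings `P`, y loadings `q`, scores `T`, original-scale
#'   `coefficients` and `intercept` (per component count 1..k), scaling
#'   vectors, fitted values and training `r_squared`.
#' @export
fit_pls <- function(X, y, n_components, drop_constant = FALSE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  kept <- seq_len(ncol(X))
  if (drop_constant) {
    v <- apply(X, 2, stats::sd)
    kept <- which(v > 0)
    if (!length(kept)) stop("all columns are constant")
    X <- X[, kept, drop = FALSE]
  }
  sc <- autoscale(X, y)
  n_components <- as.integer(n_components)
  rk <- qr(sc$X)$rank
  if (n_components < 1L || n_components > rk) {
    stop("n_components must be between 1 and rank(X) = ", rk)
  }
  p <- ncol(X)
  Xd <- sc$X; yd <- sc$y
  W <- P <- matrix(0, p, n_components)
  Tm <- matrix(0, nrow(X), n_components)
  q <- numeric(n_components)
  for (a in seq_len(n_components)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) stop("degenerate component ", a, ": X'y vanished")
    w <- w / nw
    t <- drop(Xd %*% w)
    tt <- sum(t^2)
    pl <- drop(crossprod(Xd, t)) / tt
    qa <- sum(yd * t) / tt
    Xd <- Xd - tcrossprod(t, pl)
    yd <- yd - t * qa
    W[, a] <- w; P[, a] <- pl; Tm[, a] <- t; q[a] <- qa
  }
  rownames(W) <- rownames(P) <- colnames(X)
  model <- structure(list(
    n_components = n_components, W = W, P = P, q = q, scores = Tm,
    x_center = sc$x_center, x_scale = sc$x_scale,
    y_center = sc$y_center, y_scale = sc$y_scale,
    kept_columns = kept, descriptor_names = colnames(X)),
    class = "pls_model")
  cf <- pls_coefficients(model, n_components)
  model$coefficients <- cf$beta
  model$intercept <- cf$intercept
  fitted <- drop(cf$intercept + X %*% cf$beta)
  model$fitted <- fitted
  model$r_squared <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  model
}

# Original-scale coefficients using the first k components:
# scaled-space B = W (P'W)^{-1} q_{1..k}; then undo autoscaling.
pls_coefficients <- function(model, k = model$n_components) {
  k <- as.integer(k)
  stopifnot(k >= 1L, k <= model$n_components)
  W <- model$W[, seq_len(k), drop = FALSE]
  P <- model$P[, seq_len(k), drop = FALSE]
  q <- model$q[seq_len(k)]
  Bs <- drop(W %*% solve(crossprod(P, W), q))
  beta <- Bs * model$y_scale / model$x_scale
  intercept <- model$y_center - sum(beta * model$x_center)
  list(beta = beta, intercept = intercept)
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("PLS model: %d component(s), %d descriptors, training R^2 = %.3f\n",
              x$n_components, nrow(x$W), x$r_squared))
  invisible(x)
}

#' Predict from a PLS model
#'
#' @param object A `pls_model`.
#' @param newdata Matrix or data frame with the model's descriptors (matched
#'   by name when column names are present).
#' @param k Number of components to use (default: all fitted).
#' @param ... Unused.
#' @return Numeric predictions on the original response scale.
#' @export
predict.pls_model <- function(object, newdata, k = object$n_components, ...) {
  X <- align_descriptors(object, newdata)
  cf <- pls_coefficients(object, k)
  drop(cf$intercept + X %*% cf$beta)
}

align_descriptors <- function(model, newdata) {
  X <- as.matrix(newdata)
  if (!is.null(colnames(X))) {
    missing <- setdiff(model$descriptor_names, colnames(X))
    if (length(missing)) {
      stop("newdata is missing descriptor(s): ",
           paste(missing, collapse = ", "))
    }
    X <- X[, model$descriptor_names, drop = FALSE]
  } else if (ncol(X) == length(model$kept_columns)) {
    # unnamed: assume caller already matched the fitted columns
  } else {
    X <- X[, model$kept_columns, drop = FALSE]
  }
  if (ncol(X) != length(model$descriptor_names)) {
    stop("newdata has ", ncol(X), " columns; model expects ",
         length(model$descriptor_names))
  }
  X
}

#' Leave-one-out component selection
#'
#' For every candidate component count k, each observation is held out in
#' turn, the model is refit from scratch on the remainder (re-scaling
#' included) and the held-out point predicted; RMSEP(k) is the root of the
#' mean held-out squared error. The chosen k is the smallest whose RMSEP is
#' within `parsimony_tol` (relative) of the global minimum — the parsimony
#' rule. MREP is the mean relative error `|yhat - y| / y` over folds at the
#' chosen k.
#'
#' @param X,y Descriptors and response.
#' @param k_max Largest component count to consider.
#' @param parsimony_tol Relative RMSEP slack for the parsimony rule;
#'   default 0.02.
#' @param mrep_mode `"per_observation"` (default, `mean(|e|/y)`) or
#'   `"ratio_of_means"` (`mean(|e|)/mean(y)`).
#' @return List with `rmsep_by_components`, `chosen_k`, `loo_rmsep`,
#'   `mrep`, `loo_predictions` (matrix, folds x k) and `r_squared` of the
#'   full-data fit at the chosen k.
#' @export
loo_select <- function(X, y, k_max, parsimony_tol = 0.02,
                       mrep_mode = c("per_observation", "ratio_of_means")) {
  mrep_mode <- match.arg(mrep_mode)
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 observations for LOO")
  k_max <- as.integer(k_max)
  if (k_max < 1L) stop("k_max must be >= 1")
  pred <- matrix(NA_real_, n, k_max)
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]
    ki <- min(k_max, loo_fold_rank(Xi))
    fit <- fit_pls(Xi, y[-i], n_components = ki, drop_constant = TRUE)
    for (k in seq_len(k_max)) {
      pred[i, k] <- predict(fit, X[i, , drop = FALSE], k = min(k, ki))
    }
  }
  rmsep <- sqrt(colMeans((pred - y)^2))
  chosen <- smallest_within(rmsep, parsimony_tol)
  if (mrep_mode == "per_observation") {
    if (any(y == 0)) {
      stop("response contains zeros; per-observation MREP undefined ",
           "(use mrep_mode = 'ratio_of_means')")
    }
    mrep <- mean(abs(pred[, chosen] - y) / y)
  } else {
    mrep <- mean(abs(pred[, chosen] - y)) / mean(y)
  }
  full <- fit_pls(X, y, n_components = min(chosen, loo_fold_rank(X)),
                  drop_constant = TRUE)
  list(rmsep_by_components = rmsep, chosen_k = chosen,
       loo_rmsep = rmsep[chosen], mrep = mrep, loo_predictions = pred,
       r_squared = full$r_squared, parsimony_tol = parsimony_tol)
}

loo_fold_rank <- function(X) {
  v <- apply(X, 2, stats::sd)
  Xk <- X[, v > 0, drop = FALSE]
  if (!ncol(Xk)) return(0L)
  qr(scale(Xk))$rank
}

smallest_within <- function(rmsep, tol) {
  m <- min(rmsep)
  which(rmsep <= m * (1 + tol))[1]
}

#' Repeated-split Q2 robustness validation
#'
#' Each repetition draws a random 0.8/0.2 train/test partition, selects the
#' component count by LOO-CV on the training set (same parsimony rule),
#' fits, and predicts the test set. Q2 uses the training-set mean in the
#' denominator: \deqn{Q^2 = 1 - \sum (y - \hat y)^2 / \sum (y - \bar
#' y_{train})^2.} Medians over repetitions are reported. Fully reproducible
#' from `seed`; repetition r uses an independently derived substream.
#'
#' @param X,y Descriptors and response.
#' @param train_fraction Fraction of compounds in the training partition;
#'   default 0.8.
#' @param n_reps Number of repetitions; default 1000.
#' @param k_max,parsimony_tol Component-selection rule (as [loo_select()]).
#' @param seed Master RNG seed.
#' @return List with `split_q2_median`, `split_rmse_train_median`,
#'   `split_rmse_test_median`, per-repetition vectors, `n_repetitions`,
#'   `n_degenerate_resampled` and `seed`.
#' @export
repeated_split <- function(X, y, train_fraction = 0.8, n_reps = 1000L,
                           k_max = 10L, parsimony_tol = 0.02, seed = 1L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  n_train <- round(train_fraction * n)
  if (n - n_train < 2L) stop("test partition must have at least 2 members")
  q2 <- rmse_tr <- rmse_te <- numeric(n_reps)
  chosen <- integer(n_reps)
  n_degenerate <- 0L
  for (r in seq_len(n_reps)) {
    attempt <- 0L
    repeat {
      set.seed(substream_seed(seed, r, attempt))
      idx <- sample.int(n, n_train)
      if (stats::sd(y[idx]) > 0) break
      n_degenerate <- n_degenerate + 1L
      attempt <- attempt + 1L
      if (attempt > 100L) stop("could not draw a non-degenerate partition")
    }
    Xtr <- X[idx, , drop = FALSE]; ytr <- y[idx]
    Xte <- X[-idx, , drop = FALSE]; yte <- y[-idx]
    km <- min(k_max, loo_fold_rank(Xtr))
    sel <- loo_select(Xtr, ytr, k_max = km, parsimony_tol = parsimony_tol,
                      mrep_mode = "ratio_of_means")
    fit <- fit_pls(Xtr, ytr, n_components = sel$chosen_k,
                   drop_constant = TRUE)
    pte <- predict(fit, Xte)
    q2[r] <- 1 - sum((yte - pte)^2) / sum((yte - mean(ytr))^2)
    rmse_tr[r] <- sqrt(mean((ytr - fit$fitted)^2))
    rmse_te[r] <- sqrt(mean((yte - pte)^2))
    chosen[r] <- sel$chosen_k
  }
  list(split_q2_median = stats::median(q2),
       split_rmse_train_median = stats::median(rmse_tr),
       split_rmse_test_median = stats::median(rmse_te),
       q2 = q2, rmse_train = rmse_tr, rmse_test = rmse_te,
       chosen_k = chosen, n_repetitions = n_reps,
       n_degenerate_resampled = n_degenerate, seed = seed)
}

# Deterministic per-repetition seed below 2^31.
substream_seed <- function(seed, rep, attempt = 0L) {
  ((as.integer(seed) %% 65536L) * 32749L + rep * 131L + attempt) %% 2147483647L
}

#' Variable importance in projection
#'
#' \deqn{VIP_j = \sqrt{p \sum_a SSY_a w_{ja}^2 / \sum_a SSY_a}, \quad
#'   SSY_a = q_a^2 \, t_a' t_a,} with unit-norm weight vectors. Squared VIP
#' scores sum to the number of descriptors.
#'
#' @param model A fitted `pls_model`.
#' @return Data frame (`descriptor`, `vip`) sorted by decreasing VIP.
#' @export
vip <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  ssy <- model$q^2 * colSums(model$scores^2)
  w2 <- sweep(model$W^2, 2, colSums(model$W^2), "/")
  p <- nrow(model$W)
  v <- sqrt(p * drop(w2 %*% ssy) / sum(ssy))
  out <- data.frame(descriptor = rownames(model$W), vip = v,
                    row.names = NULL)
  out[order(-out$vip), ]
}

#' Latent-space coordinates and loadings for plotting
#'
#' Scores for (possibly new) compounds are computed with the model's
#' rotation `R = W (P'W)^{-1}` applied to autoscaled descriptors, which
#' reproduces the training scores exactly on the training data.
#'
#' @param model A fitted `pls_model`.
#' @param X Descriptor matrix (training or new compounds).
#' @return List with `scores` (n x k) and `loadings` (p x k, the X
#'   loadings).
#' @export
latent_export <- function(model, X) {
  X <- align_descriptors(model, X)
  Xs <- sweep(sweep(X, 2, model$x_center), 2, model$x_scale, "/")
  R <- model$W %*% solve(crossprod(model$P, model$W))
  scores <- Xs %*% R
  colnames(scores) <- colnames(model$P) <- paste0("comp", seq_len(model$n_components))
  list(scores = scores, loadings = model$P)
}

#' Load a descriptor matrix and response from CSV
#'
#' The descriptor CSV has compounds as rows (first column = compound id,
#' remaining columns = descriptors); the response CSV has columns
#' `compound` and a response value column (second column used). An optional
#' keep-list file (one descriptor name per line) restricts the descriptor
#' set; constant columns are dropped with a message.
#'
#' @param descriptor_csv,response_csv File paths.
#' @param keep_list Optional path to a descriptor keep-list.
#' @return List with `X` (named matrix), `y`, `compounds`.
#' @export
read_qspr_tables <- function(descriptor_csv, response_csv,
                             keep_list = NULL) {
  d <- utils::read.csv(descriptor_csv, stringsAsFactors = FALSE,
                       check.names = FALSE)
  r <- utils::read.csv(response_csv, stringsAsFactors = FALSE)
  ids <- as.character(d[[1]])
  X <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(X) <- "double"
  rownames(X) <- ids
  m <- match(ids, as.character(r[[1]]))
  if (anyNA(m)) {
    stop("compounds without response: ",
         paste(ids[is.na(m)], collapse = ", "))
  }
  y <- as.numeric(r[[2]][m])
  if (!is.null(keep_list)) {
    keep <- readLines(keep_list)
    keep <- keep[nzchar(trimws(keep))]
    missing <- setdiff(keep, colnames(X))
    if (length(missing)) {
      stop("keep-list descriptors absent from matrix: ",
           paste(missing, collapse = ", "))
    }
    X <- X[, keep, drop = FALSE]
  }
  if (anyNA(X)) stop("descriptor matrix contains missing values")
  v <- apply(X, 2, stats::sd)
  if (any(v == 0)) {
    message("dropping ", sum(v == 0), " constant descriptor(s)")
    X <- X[, v > 0, drop = FALSE]
  }
  if (nrow(X) < 5L) stop("need at least 5 compounds")
  list(X = X, y = y, compounds = ids)
}
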