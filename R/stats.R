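# Statistical comparison of per-replicate mean APR-SASA distributions:
# Bartlett homoscedasticity gate, Kruskal-Wallis or Welch omnibus, Dunn
# post-hoc. All tests are implemented from the standard formulas (the base
# stats implementations serve as independent oracles in the test suite).

check_groups <- function(groups, min_size = 2L) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need a list of at least 2 groups")
  }
  groups <- lapply(groups, as.numeric)
  if (any(vapply(groups, length, 1L) < min_size)) {
    stop("every group needs at least ", min_size, " values")
  }
  if (!all(vapply(groups, function(g) all(is.finite(g)), TRUE))) {
    stop("all values must be finite")
  }
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_along(groups))
  groups
}

#' Bartlett's test of homogeneity of variances
#'
#' Used as the gate that decides between the rank-based and the
#' heteroscedastic omnibus test.
#'
#' @param groups Named list of numeric vectors (each length >= 2).
#' @return List with `statistic` (chi-square), `df` and `p`.
#' @export
bartlett_gate <- function(groups) {
  groups <- check_groups(groups)
  k <- length(groups)
  ni <- vapply(groups, length, 1L)
  vi <- vapply(groups, stats::var, 1)
  if (any(vi == 0)) {
    stop("a group has zero variance; Bartlett's statistic is undefined ",
         "(jitter the data or use the omnibus test directly)")
  }
  N <- sum(ni)
  sp2 <- sum((ni - 1) * vi) / (N - k)
  stat <- ((N - k) * log(sp2) - sum((ni - 1) * log(vi))) /
    (1 + (sum(1 / (ni - 1)) - 1 / (N - k)) / (3 * (k - 1)))
  list(statistic = stat, df = k - 1,
       p = stats::pchisq(stat, k - 1, lower.tail = FALSE))
}

# Pooled midranks and the tie-correction term sum(t^3 - t).
pooled_ranks <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  r <- rank(x)                      # midranks
  tt <- table(x)
  list(ranks = split(r, rep(seq_along(groups),
                            vapply(groups, length, 1L))),
       tie_sum = sum(tt^3 - tt), N = length(x))
}

kw_statistic <- function(groups) {
  pr <- pooled_ranks(groups)
  ni <- vapply(groups, length, 1L)
  N <- pr$N
  Ri <- vapply(pr$ranks, sum, 1)
  H <- 12 / (N * (N + 1)) * sum(Ri^2 / ni) - 3 * (N + 1)
  C <- 1 - pr$tie_sum / (N^3 - N)
  if (C > 0) H / C else 0
}

#' Kruskal-Wallis rank ANOVA
#'
#' H uses midranks with the standard tie correction. For total n <= 10 an
#' exact permutation p (enumeration of all group assignments) is available.
#'
#' @param groups Named list of numeric vectors.
#' @param exact Compute the exact permutation p when total n <= 10.
#' @return List with `H`, `df`, `p` and, when computed, `p_exact`.
#' @export
kruskal_wallis <- function(groups, exact = FALSE) {
  groups <- check_groups(groups, min_size = 1L)
  ni <- vapply(groups, length, 1L)
  N <- sum(ni)
  if (N < 3L) stop("need at least 3 observations in total")
  x <- unlist(groups, use.names = FALSE)
  if (length(unique(x)) == 1L) {
    return(list(H = 0, df = length(groups) - 1L, p = 1))
  }
  H <- kw_statistic(groups)
  out <- list(H = H, df = length(groups) - 1L,
              p = stats::pchisq(H, length(groups) - 1L, lower.tail = FALSE))
  if (exact) {
    if (N > 10L) stop("exact permutation p only supported for total n <= 10")
    out$p_exact <- kw_exact_p(x, ni, H)
  }
  out
}

# Exact permutation p: fraction of assignments of the pooled values to
# groups of the observed sizes with H >= observed (>= up to tolerance).
kw_exact_p <- function(x, ni, H_obs) {
  idx_perms <- assignments(seq_along(x), ni)
  hs <- vapply(idx_perms, function(idx) {
    g <- split(x[idx], rep(seq_along(ni), ni))
    kw_statistic(g)
  }, 1)
  mean(hs >= H_obs - 1e-10)
}

# All distinct ways to partition `ids` into ordered groups of sizes `ni`,
# as permutations of ids (combinatorial recursion; intended for n <= 10).
assignments <- function(ids, ni) {
  if (length(ni) == 1L) return(list(ids))
  first <- utils::combn(ids, ni[1], simplify = FALSE)
  out <- list()
  for (f in first) {
    rest <- assignments(setdiff(ids, f), ni[-1])
    out <- c(out, lapply(rest, function(r) c(f, r)))
  }
  out
}

#' Welch's heteroscedastic one-way ANOVA
#'
#' @param groups Named list of numeric vectors (each length >= 2, positive
#'   variance).
#' @return List with `F_star`, `df1`, `df2`, `p`.
#' @export
welch_anova <- function(groups) {
  groups <- check_groups(groups)
  vi <- vapply(groups, stats::var, 1)
  if (any(vi == 0)) stop("a group has zero variance; Welch ANOVA undefined")
  ni <- vapply(groups, length, 1L)
  mi <- vapply(groups, mean, 1)
  k <- length(groups)
  wi <- ni / vi
  W <- sum(wi)
  mw <- sum(wi * mi) / W
  A <- sum(wi * (mi - mw)^2) / (k - 1)
  B <- 2 * (k - 2) / (k^2 - 1) * sum((1 - wi / W)^2 / (ni - 1))
  Fs <- A / (1 + B)
  df2 <- (k^2 - 1) / (3 * sum((1 - wi / W)^2 / (ni - 1)))
  list(F_star = Fs, df1 = k - 1, df2 = df2,
       p = stats::pf(Fs, k - 1, df2, lower.tail = FALSE))
}

#' Dunn's post-hoc test on pooled midranks
#'
#' Pairwise z statistics from the pooled midranks with the tie correction
#' \eqn{\sum (t^3 - t) / (12 (N - 1))}; two-sided normal p values with an
#' optional multiplicity adjustment.
#'
#' @param groups Named list of numeric vectors.
#' @param adjust Any method of [stats::p.adjust()]; default `"none"` (the
#'   convention of reporting raw thresholds).
#' @param alpha_levels Significance levels flagged in the output.
#' @return Data frame with one row per pair: `group1`, `group2`, `z`,
#'   `p_raw`, `p_adjusted`, and a star column per alpha level.
#' @export
dunn_posthoc <- function(groups, adjust = "none",
                         alpha_levels = c(0.05, 0.01)) {
  groups <- check_groups(groups, min_size = 1L)
  pr <- pooled_ranks(groups)
  ni <- vapply(groups, length, 1L)
  N <- pr$N
  rbar <- vapply(pr$ranks, mean, 1)
  tie_term <- pr$tie_sum / (12 * (N - 1))
  pairs <- utils::combn(seq_along(groups), 2)
  z <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    se2 <- (N * (N + 1) / 12 - tie_term) * (1 / ni[i] + 1 / ni[j])
    if (se2 <= 0) return(0)
    (rbar[i] - rbar[j]) / sqrt(se2)
  })
  p_raw <- 2 * stats::pnorm(-abs(z))
  out <- data.frame(group1 = names(groups)[pairs[1, ]],
                    group2 = names(groups)[pairs[2, ]],
                    z = z, p_raw = p_raw,
                    p_adjusted = stats::p.adjust(p_raw, method = adjust))
  for (a in alpha_levels) {
    out[[sprintf("sig_%g", a)]] <- out$p_adjusted < a
  }
  out
}

#' Gated comparison of excipient systems against a control
#'
#' Mirrors the published procedure: Bartlett's test across all groups gates
#' the omnibus — Kruskal-Wallis when variances look homogeneous (Bartlett
#' p >= `alpha_gate`), Welch's heteroscedastic ANOVA otherwise — followed by
#' Dunn's post-hoc on all pairs.
#'
#' @param systems Named list of numeric vectors (per-replicate mean APR
#'   SASA), including the control.
#' @param control Name of the control group in `systems`.
#' @param alpha_gate Gate level for Bartlett; default 0.05.
#' @param alpha_levels Post-hoc significance levels; default 0.05 and 0.01.
#' @param adjust p adjustment for the post-hoc; default `"none"`.
#' @return Object of class `"stat_report"`: list with `gate`, `omnibus`
#'   (including `method`), `posthoc` (full pairwise table), `vs_control`
#'   (rows involving the control), and a logical significance matrix per
#'   alpha level.
#' @export
compare_all <- function(systems, control, alpha_gate = 0.05,
                        alpha_levels = c(0.05, 0.01), adjust = "none") {
  systems <- check_groups(systems)
  if (!control %in% names(systems)) {
    stop("control group '", control, "' not found")
  }
  gate <- bartlett_gate(systems)
  if (gate$p < alpha_gate) {
    om <- welch_anova(systems)
    omnibus <- list(method = "welch_anova", statistic = om$F_star,
                    df = c(om$df1, om$df2), p = om$p)
  } else {
    om <- kruskal_wallis(systems)
    omnibus <- list(method = "kruskal_wallis", statistic = om$H,
                    df = om$df, p = om$p)
  }
  ph <- dunn_posthoc(systems, adjust = adjust, alpha_levels = alpha_levels)
  k <- length(systems)
  sig <- lapply(alpha_levels, function(a) {
    m <- matrix(FALSE, k, k, dimnames = list(names(systems), names(systems)))
    col <- sprintf("sig_%g", a)
    for (r in seq_len(nrow(ph))) {
      m[ph$group1[r], ph$group2[r]] <- m[ph$group2[r], ph$group1[r]] <- ph[[col]][r]
    }
    m
  })
  names(sig) <- sprintf("alpha_%g", alpha_levels)
  structure(list(gate = gate, omnibus = omnibus, posthoc = ph,
                 vs_control = ph[ph$group1 == control | ph$group2 == control, ],
                 significance = sig, control = control,
                 alpha_gate = alpha_gate),
            class = "stat_report")
}

#' @export
print.stat_report <- function(x, ...) {
  cat(sprintf("Gate: Bartlett chi^2 = %.3f, p = %.4f -> %s\n",
              x$gate$statistic, x$gate$p, x$omnibus$method))
  cat(sprintf("Omnibus %s: statistic = %.3f, p = %.4f\n",
              x$omnibus$method, x$omnibus$statistic, x$omnibus$p))
  cat("Post-hoc (Dunn) vs control:\n")
  print(x$vs_control, row.names = FALSE)
  invisible(x)
}

#' Serialize a stat_report to JSON
#' @param report A `stat_report`.
#' @param path Output path.
#' @export
write_stat_report <- function(report, path) {
  jsonlite::write_json(
    list(gate = report$gate, omnibus = report$omnibus,
         posthoc = report$posthoc, control = report$control,
         alpha_gate = report$alpha_gate),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
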