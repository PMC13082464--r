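# Interaction-term regression for one candidate edge. For two groups the
# model is
#
#   u = b0 + b1 v + b2 k + b3 (v * k) + e,    k in {0, 1}
#
# and the differential interaction effect b3 is tested with a two-sided t
# test (OLS) or a Wald t test on the Huber M-estimate (robust). For K >= 3
# groups an ANCOVA homogeneity-of-slopes F-test compares group-specific
# slopes against a common slope. Samples with a missing value in either
# endpoint are dropped pairwise; no imputation is performed.

untestable <- function(reason, method, n_used = NA_integer_) {
  structure(list(n_used = n_used, beta = rep(NA_real_, 4), se3 = NA_real_,
                 stat = NA_real_, df1 = NA_real_, df2 = NA_real_,
                 p = NA_real_, method = method, testable = FALSE,
                 reason = reason),
            class = "edge_test")
}

# pairwise-complete rows + design sanity shared by all fits
prepare_edge_data <- function(u, v, k, min_per_group, method) {
  k <- as.character(k)
  ok <- is.finite(u) & is.finite(v) & !is.na(k)
  u <- u[ok]; v <- v[ok]; k <- k[ok]
  g <- factor(k, levels = sort(unique(k)))
  K <- nlevels(g)
  n <- length(u)
  if (K < 2)
    return(untestable("fewer than two groups after missing-data removal",
                      method, n))
  tab <- table(g)
  if (any(tab < min_per_group))
    return(untestable(sprintf("group below minimum size %d", min_per_group),
                      method, n))
  if (n < 2 * K + 2)
    return(untestable("too few samples for residual degrees of freedom",
                      method, n))
  for (lev in levels(g)) {
    vg <- v[g == lev]
    if (max(vg) - min(vg) <= 0)
      return(untestable(sprintf("covariate constant within group '%s'", lev),
                        method, n))
  }
  list(u = u, v = v, g = g, K = K, n = n)
}

# least-squares work-horse: same algebra as summary.lm, via the pivoted QR
ls_fit <- function(X, u) {
  fit <- stats::lm.fit(X, u)
  if (fit$rank < ncol(X)) return(NULL)
  piv <- fit$qr$pivot
  R <- qr.R(fit$qr)
  cov_unscaled <- matrix(NA_real_, ncol(X), ncol(X))
  cov_unscaled[piv, piv] <- chol2inv(R)
  list(coef = fit$coefficients, rss = sum(fit$residuals^2),
       cov_unscaled = cov_unscaled)
}

#' Ordinary least-squares interaction test (two groups)
#'
#' Fits `u ~ v * k` by OLS with k coded 0/1 (first group label in sorted
#' order is the reference) and tests H0: b3 = 0 two-sided.
#'
#' @param u,v Numeric expression vectors for the response and covariate
#'   entity of the edge.
#' @param k Group membership vector with exactly two distinct labels.
#' @param min_per_group Minimum samples required per group (default 3; total
#'   minimum is 6, leaving >= 2 residual degrees of freedom).
#' @return Object of class `edge_test`: `n_used`, `beta` (b0..b3), `se3`,
#'   `stat` (t), `df1`/`df2`, `p`, `method`, `testable`, `reason`.
#' @export
fit_interaction_ols <- function(u, v, k, min_per_group = 3) {
  d <- prepare_edge_data(u, v, k, min_per_group, "ols")
  if (inherits(d, "edge_test")) return(d)
  if (d$K != 2)
    return(untestable("OLS interaction path requires exactly two groups", "ols",
                      d$n))
  k01 <- as.numeric(d$g == levels(d$g)[2])
  X <- cbind(1, d$v, k01, d$v * k01)
  fit <- ls_fit(X, d$u)
  if (is.null(fit))
    return(untestable("rank-deficient design", "ols", d$n))
  df2 <- d$n - 4
  s2 <- fit$rss / df2
  se3 <- sqrt(s2 * fit$cov_unscaled[4, 4])
  # an (essentially) perfect fit has no residual scale to test against
  degenerate <- fit$rss <= 1e-12 * sum(d$u^2)
  if (!is.finite(se3) || se3 <= 0 || degenerate) {
    out <- untestable("degenerate fit (zero residual variance)", "ols", d$n)
    out$beta <- stats::setNames(as.numeric(fit$coef), paste0("beta", 0:3))
    return(out)
  }
  tstat <- fit$coef[4] / se3
  structure(list(n_used = d$n,
                 beta = stats::setNames(as.numeric(fit$coef),
                                        paste0("beta", 0:3)),
                 se3 = se3, stat = as.numeric(tstat), df1 = 1, df2 = df2,
                 p = as.numeric(2 * stats::pt(-abs(tstat), df2)),
                 method = "ols", testable = TRUE, reason = NA_character_),
            class = "edge_test")
}

#' Robust (Huber) interaction test (two groups)
#'
#' Same model as [fit_interaction_ols()] but estimated by Huber M-estimation
#' (tuning constant 1.345, MAD scale, IRLS tolerance 1e-8, at most 50
#' iterations) via [MASS::rlm()]. Classical `rlm` summaries do not emit
#' p-values; the b3 p-value is the standard Wald reconstruction, t = b3/se
#' against a t distribution with `n_used - 4` degrees of freedom.
#'
#' @inheritParams fit_interaction_ols
#' @return An `edge_test` object (method `"robust"`); non-convergence is
#'   flagged untestable.
#' @export
fit_interaction_robust <- function(u, v, k, min_per_group = 3) {
  d <- prepare_edge_data(u, v, k, min_per_group, "robust")
  if (inherits(d, "edge_test")) return(d)
  if (d$K != 2)
    return(untestable("robust interaction path requires exactly two groups",
                      "robust", d$n))
  k01 <- as.numeric(d$g == levels(d$g)[2])
  X <- cbind(`(Intercept)` = 1, v = d$v, k = k01, `v:k` = d$v * k01)
  fit <- tryCatch(
    MASS::rlm(X, d$u, psi = MASS::psi.huber, k = 1.345,
              maxit = 50, acc = 1e-8),
    error = function(e) NULL)
  if (is.null(fit) || !isTRUE(fit$converged))
    return(untestable("robust fit did not converge", "robust", d$n))
  sm <- suppressWarnings(summary(fit, method = "XtX"))$coefficients
  se3 <- sm[4, "Std. Error"]
  if (!is.finite(se3) || se3 <= 0)
    return(untestable("degenerate robust fit", "robust", d$n))
  df2 <- d$n - 4
  tstat <- sm[4, "Value"] / se3
  structure(list(n_used = d$n,
                 beta = stats::setNames(as.numeric(sm[, "Value"]),
                                        paste0("beta", 0:3)),
                 se3 = se3, stat = as.numeric(tstat), df1 = 1, df2 = df2,
                 p = as.numeric(2 * stats::pt(-abs(tstat), df2)),
                 method = "robust", testable = TRUE, reason = NA_character_),
            class = "edge_test")
}

#' ANCOVA interaction F-test (three or more groups)
#'
#' Compares the full model with group-specific slopes (`u ~ v * k`) against
#' the reduced common-slope model (`u ~ v + k`) with an F-test on
#' `(K - 1, n_used - 2K)` degrees of freedom. With exactly two groups the
#' call delegates to the t-test path of [fit_interaction_ols()] (t^2 = F).
#'
#' @inheritParams fit_interaction_ols
#' @param k Group membership vector with K >= 2 distinct labels.
#' @return An `edge_test` object (method `"ancova"`, or `"ols"` when K = 2).
#' @export
fit_interaction_ancova <- function(u, v, k, min_per_group = 3) {
  d <- prepare_edge_data(u, v, k, min_per_group, "ancova")
  if (inherits(d, "edge_test")) return(d)
  if (d$K == 2) return(fit_interaction_ols(u, v, k, min_per_group))
  X_full <- stats::model.matrix(~ v * g, data = list(v = d$v, g = d$g))
  X_red <- stats::model.matrix(~ v + g, data = list(v = d$v, g = d$g))
  full <- ls_fit(X_full, d$u)
  red <- ls_fit(X_red, d$u)
  if (is.null(full) || is.null(red))
    return(untestable("rank-deficient design", "ancova", d$n))
  df1 <- d$K - 1
  df2 <- d$n - 2 * d$K
  if (full$rss <= 1e-12 * sum(d$u^2))
    return(untestable("degenerate fit (zero residual variance)", "ancova",
                      d$n))
  Fstat <- ((red$rss - full$rss) / df1) / (full$rss / df2)
  structure(list(n_used = d$n, beta = rep(NA_real_, 4), se3 = NA_real_,
                 stat = as.numeric(Fstat), df1 = df1, df2 = df2,
                 p = stats::pf(Fstat, df1, df2, lower.tail = FALSE),
                 method = "ancova", testable = TRUE, reason = NA_character_),
            class = "edge_test")
}

# dispatch used by the pipeline: K = 2 -> ols/robust, K >= 3 -> ancova
fit_interaction <- function(u, v, k, method = c("ols", "robust"),
                            min_per_group = 3) {
  method <- match.arg(method)
  K <- length(unique(as.character(k[!is.na(k)])))
  if (K >= 3) return(fit_interaction_ancova(u, v, k, min_per_group))
  if (method == "robust") fit_interaction_robust(u, v, k, min_per_group)
  else fit_interaction_ols(u, v, k, min_per_group)
}

#' Multiple-testing correction
#'
#' Adjusts a vector of raw p-values. Bonferroni (the default throughout the
#' package), Holm and Benjamini-Hochberg delegate to [stats::p.adjust()];
#' Storey's q-values use the fixed-lambda = 0.5 estimator
#' pi0 = mean(p > 0.5) / 0.5, floored at 1/m to keep the single-test case
#' equal to the raw p-value, and are pi0 times the BH adjustment.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param method One of `"bonferroni"`, `"bh"`, `"holm"`, `"storey"`,
#'   `"none"`.
#' @return Adjusted p-values, clipped to 1, in the input order.
#' @examples
#' adjust_pvalues(c(0.01, 0.02, 0.04), "bh")
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "bh", "holm",
                                         "storey", "none")) {
  method <- match.arg(method)
  p <- as.numeric(p)
  if (length(p) == 0) return(numeric(0))
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop_diffnetx("p-values must lie in [0, 1]", "diffnetx_error_bad_pvalues")
  switch(method,
    none = p,
    bonferroni = stats::p.adjust(p, "bonferroni"),
    holm = stats::p.adjust(p, "holm"),
    bh = stats::p.adjust(p, "BH"),
    storey = {
      m <- sum(!is.na(p))
      pi0 <- min(1, max(mean(p > 0.5, na.rm = TRUE) / 0.5, 1 / m))
      pmin(1, pi0 * stats::p.adjust(p, "BH"))
    })
}
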