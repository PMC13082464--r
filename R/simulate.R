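# Synthetic edge data under the interaction model, and the grid benchmark
# measuring sensitivity/specificity of differential-edge detection under
# varying noise, outlier contamination and interaction strength. Each
# replicate simulates one small edge family (true + null edges), applies the
# chosen fit and the family-wise correction, and scores detections against
# the known ground truth.
#
# The simulation protocol frozen here: n_per_group = 500, families of
# 2 true + 8 null edges, covariate v ~ N(0, 1), generating coefficients
# (b0, b1, b2) = (0, 1, 0) with only b3 varied, outliers shifted by
# +/- 5 * noise_sd, Bonferroni correction at adjusted p < 0.05. These values
# were fixed once by a power analysis of the weak- and strong-signal regimes
# (see the methods vignette) and are exposed as ordinary configuration.

#' Simulation configuration for one benchmark condition
#'
#' @param n_per_group Samples per group (default 500).
#' @param noise_sd Residual standard deviation (> 0).
#' @param outlier_fraction Fraction of samples contaminated, in `[0, 1)`.
#' @param beta Generating coefficients `(b0, b1, b2, b3)`; null edges are
#'   simulated with b3 = 0.
#' @param n_true_edges,n_null_edges Edges per simulated family (defaults 2
#'   and 8).
#' @param outlier_magnitude Outlier shift in units of `noise_sd` (default 5).
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_per_group = 500, noise_sd = 0.5,
                              outlier_fraction = 0.1,
                              beta = c(0, 1, 0, 1),
                              n_true_edges = 2, n_null_edges = 8,
                              outlier_magnitude = 5) {
  stopifnot(n_per_group >= 3, noise_sd > 0,
            outlier_fraction >= 0, outlier_fraction < 1,
            length(beta) == 4, n_true_edges >= 0, n_null_edges >= 0,
            outlier_magnitude > 0)
  structure(list(n_per_group = n_per_group, noise_sd = noise_sd,
                 outlier_fraction = outlier_fraction, beta = beta,
                 n_true_edges = n_true_edges, n_null_edges = n_null_edges,
                 outlier_magnitude = outlier_magnitude),
            class = "simulation_config")
}

#' Simulate one edge under the interaction model
#'
#' Draws `v ~ N(0, 1)`, a balanced binary group vector `k`, and
#' `u = b0 + b1 v + b2 k + b3 (v * k) + e` with `e ~ N(0, noise_sd^2)`,
#' then contaminates `u` with [inject_outliers()].
#'
#' @param config A [simulation_config()].
#' @param beta3 Override for the interaction coefficient (e.g. 0 for a null
#'   edge); defaults to `config$beta[4]`.
#' @return List with `u`, `v`, `k` (0/1 integer) and `outlier_idx`.
#' @export
simulate_edge <- function(config, beta3 = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  b <- config$beta
  if (!is.null(beta3)) b[4] <- beta3
  n <- 2L * config$n_per_group
  v <- stats::rnorm(n)
  k <- rep(c(0L, 1L), each = config$n_per_group)
  u <- b[1] + b[2] * v + b[3] * k + b[4] * v * k +
    stats::rnorm(n, 0, config$noise_sd)
  contaminated <- inject_outliers(u, config$outlier_fraction,
                                  config$outlier_magnitude * config$noise_sd)
  list(u = contaminated$values, v = v, k = k,
       outlier_idx = contaminated$idx)
}

#' Contaminate a vector with gross outliers
#'
#' Picks `floor(fraction * n)` positions uniformly without replacement and
#' shifts each by `magnitude` with a random sign.
#'
#' @param u Numeric vector.
#' @param fraction Fraction of positions to contaminate, in `[0, 1)`.
#' @param magnitude Absolute shift applied to each contaminated position
#'   (callers typically pass a multiple of the noise SD).
#' @param seed Optional integer seed.
#' @return List with `values` (contaminated vector) and `idx` (contaminated
#'   positions, possibly empty).
#' @export
inject_outliers <- function(u, fraction, magnitude, seed = NULL) {
  if (fraction < 0 || fraction >= 1)
    stop_diffnetx("fraction must be in [0, 1)",
                  "diffnetx_error_bad_fraction")
  if (!is.null(seed)) set.seed(seed)
  m <- floor(fraction * length(u))
  if (m == 0) return(list(values = u, idx = integer(0)))
  idx <- sample.int(length(u), m)
  u[idx] <- u[idx] + sample(c(-1, 1), m, replace = TRUE) * magnitude
  list(values = u, idx = sort(idx))
}

#' Default benchmark grid
#'
#' The full factorial grid: noise SD in {0.5, 0.8, 1.2}, outlier fraction in
#' {0.10, 0.20, 0.30}, interaction strength b3 in {0.5, 0.75, 1.0}.
#'
#' @return Data frame with columns `noise_sd`, `outlier_fraction`, `beta3`.
#' @export
default_benchmark_grid <- function() {
  expand.grid(noise_sd = c(0.5, 0.8, 1.2),
              outlier_fraction = c(0.10, 0.20, 0.30),
              beta3 = c(0.5, 0.75, 1.0),
              KEEP.OUT.ATTRS = FALSE)
}

clopper_pearson <- function(x, n, level = 0.95) {
  a <- (1 - level) / 2
  lo <- if (x == 0) 0 else stats::qbeta(a, x, n - x + 1)
  hi <- if (x == n) 1 else stats::qbeta(1 - a, x + 1, n - x)
  c(lo, hi)
}

#' Sensitivity/specificity benchmark on simulated edge families
#'
#' For every grid condition, repeatedly simulates an edge family
#' (`n_true_edges` with the condition's b3 plus `n_null_edges` with b3 = 0),
#' contaminates the responses, tests every edge with the chosen fit, applies
#' one family-wise correction per replicate, and scores detections against
#' ground truth: sensitivity = TP / (TP + FN) over true edges, specificity =
#' TN / (TN + FP) over null edges.
#'
#' @param grid Data frame with columns `noise_sd`, `outlier_fraction`,
#'   `beta3` (default [default_benchmark_grid()]).
#' @param method `"ols"` or `"robust"`.
#' @param alpha_adj Significance level on adjusted p-values (default 0.05).
#' @param correction Multiple-testing method (default Bonferroni).
#' @param replicates Simulated families per condition (>= 1).
#' @param n_per_group,n_true_edges,n_null_edges,outlier_magnitude Protocol
#'   knobs, see [simulation_config()].
#' @param seed Optional integer seed.
#' @param detail Also return the per-replicate TP/FP counts.
#' @return Data frame with one row per condition: the grid columns, counts
#'   TP/FN/TN/FP, `sensitivity`, `specificity` and Clopper-Pearson 95%
#'   interval bounds. With `detail = TRUE`, attribute `detail` holds a list
#'   of per-condition replicate count matrices.
#' @export
run_benchmark <- function(grid = default_benchmark_grid(),
                          method = c("ols", "robust"), alpha_adj = 0.05,
                          correction = "bonferroni", replicates = 200,
                          n_per_group = 500, n_true_edges = 2,
                          n_null_edges = 8, outlier_magnitude = 5,
                          seed = NULL, detail = FALSE) {
  method <- match.arg(method)
  if (replicates < 1)
    stop_diffnetx("replicates must be >= 1", "diffnetx_error_bad_replicates")
  if (!is.null(seed)) set.seed(seed)
  fitfun <- if (method == "robust") fit_interaction_robust
            else fit_interaction_ols
  rows <- vector("list", nrow(grid))
  details <- vector("list", nrow(grid))
  for (ci in seq_len(nrow(grid))) {
    cfg <- simulation_config(n_per_group = n_per_group,
                             noise_sd = grid$noise_sd[ci],
                             outlier_fraction = grid$outlier_fraction[ci],
                             beta = c(0, 1, 0, grid$beta3[ci]),
                             n_true_edges = n_true_edges,
                             n_null_edges = n_null_edges,
                             outlier_magnitude = outlier_magnitude)
    rep_counts <- matrix(0L, replicates, 4,
                         dimnames = list(NULL, c("TP", "FN", "TN", "FP")))
    for (r in seq_len(replicates)) {
      truth <- rep(c(TRUE, FALSE), c(cfg$n_true_edges, cfg$n_null_edges))
      p <- vapply(truth, function(is_true) {
        e <- simulate_edge(cfg, beta3 = if (is_true) cfg$beta[4] else 0)
        ft <- fitfun(e$u, e$v, e$k)
        if (isTRUE(ft$testable)) ft$p else NA_real_
      }, 1)
      ok <- !is.na(p)
      p_adj <- rep(NA_real_, length(p))
      p_adj[ok] <- adjust_pvalues(p[ok], correction)
      hit <- !is.na(p_adj) & p_adj < alpha_adj
      rep_counts[r, ] <- c(sum(hit & truth), sum(!hit & truth),
                           sum(!hit & !truth), sum(hit & !truth))
    }
    tot <- colSums(rep_counts)
    ci_sens <- clopper_pearson(tot["TP"], tot["TP"] + tot["FN"])
    ci_spec <- clopper_pearson(tot["TN"], tot["TN"] + tot["FP"])
    rows[[ci]] <- data.frame(
      noise_sd = grid$noise_sd[ci],
      outlier_fraction = grid$outlier_fraction[ci],
      beta3 = grid$beta3[ci], method = method, replicates = replicates,
      TP = tot["TP"], FN = tot["FN"], TN = tot["TN"], FP = tot["FP"],
      sensitivity = if (tot["TP"] + tot["FN"] > 0)
        unname(tot["TP"] / (tot["TP"] + tot["FN"])) else NA_real_,
      specificity = if (tot["TN"] + tot["FP"] > 0)
        unname(tot["TN"] / (tot["TN"] + tot["FP"])) else NA_real_,
      sens_lo = ci_sens[1], sens_hi = ci_sens[2],
      spec_lo = ci_spec[1], spec_hi = ci_spec[2],
      stringsAsFactors = FALSE)
    details[[ci]] <- rep_counts
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (detail) attr(out, "detail") <- details
  out
}
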