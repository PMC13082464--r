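# Adaptive threshold selection. The activation threshold tau trades network
# size against the stringency of multiple-testing correction: low thresholds
# admit many nodes (and a heavy correction penalty, the over-connected
# "hairball" regime), high thresholds fragment the network. The scan sweeps
# tau over quantiles of the pooled per-(feature, group) summary distribution
# and keeps the value maximizing the number of significant edges after
# correction. Quantiles below 0.35 sit in the unstable noise regime and are
# rejected under the default floor rather than silently clamped.

#' Default quantile grid for the percolation scan
#'
#' @param from,to,by Grid limits and step; defaults 0.35 to 0.95 by 0.05.
#' @return Numeric vector of quantiles.
#' @export
default_quantile_grid <- function(from = 0.35, to = 0.95, by = 0.05) {
  seq(from, to, by = by)
}

#' Percolation scan for the layer activation threshold
#'
#' For every quantile q of the grid, sets tau to the q-quantile (linear
#' interpolation between order statistics) of the pooled per-(feature, group)
#' summary values, runs the full downstream pipeline (activation,
#' common-edge removal, interaction tests, family-wise correction) and
#' records the significant-edge count. The returned activation is the grid
#' argmax, with ties broken toward the higher quantile (the stricter,
#' sparser network).
#'
#' @param layer An [expression_layer()].
#' @param labels A [group_labels()].
#' @param net A [reference_network()].
#' @param quantile_grid Quantiles to scan, all within `[floor_quantile, 1)`.
#' @param floor_quantile Minimum admissible quantile (default 0.35); grid
#'   points below it raise an error.
#' @param statistic Per-group summary statistic, `"median"` (default) or
#'   `"mean"`.
#' @param method Edge regression flavour, `"ols"` or `"robust"`.
#' @param alpha_adj Significance level on adjusted p-values.
#' @param correction Multiple-testing method (default Bonferroni).
#' @param min_per_group Minimum per-group sample size for a testable edge.
#' @return Object of class `layer_activation`: `tau`, `quantile`,
#'   `group_summaries`, `active_sets`, `families` (edge families at the
#'   selected threshold) and `scan_trace` (data frame with columns
#'   `quantile`, `tau`, `n_active_nodes`, `n_candidate_edges`,
#'   `n_significant_edges`).
#' @export
percolation_scan <- function(layer, labels, net,
                             quantile_grid = default_quantile_grid(),
                             floor_quantile = 0.35,
                             statistic = c("median", "mean"),
                             method = c("ols", "robust"),
                             alpha_adj = 0.05, correction = "bonferroni",
                             min_per_group = 3) {
  statistic <- match.arg(statistic)
  method <- match.arg(method)
  if (length(quantile_grid) == 0)
    stop_diffnetx("quantile grid is empty", "diffnetx_error_empty_grid")
  if (any(quantile_grid < floor_quantile))
    stop_diffnetx(
      sprintf("quantile grid contains values below the %.2f floor",
              floor_quantile),
      "diffnetx_error_grid_below_floor")
  if (any(quantile_grid >= 1))
    stop_diffnetx("quantiles must be < 1", "diffnetx_error_bad_grid")
  quantile_grid <- sort(unique(quantile_grid))

  summaries <- compute_group_summaries(layer, labels, statistic)
  pooled <- summaries[is.finite(summaries)]
  net_sub <- subset_to_layer(net, layer$feature_ids)
  cache <- new.env(parent = emptyenv())

  scan <- lapply(quantile_grid, function(q) {
    tau <- stats::quantile(pooled, q, type = 7, names = FALSE)
    at <- families_at_tau(layer, labels, summaries, tau, net_sub, method,
                          alpha_adj, correction, min_per_group, cache)
    list(q = q, tau = tau, at = at)
  })
  trace <- data.frame(
    quantile = vapply(scan, `[[`, 1, "q"),
    tau = vapply(scan, `[[`, 1, "tau"),
    n_active_nodes = vapply(scan, function(s)
      length(unique(unlist(s$at$active))), 1L),
    n_candidate_edges = vapply(scan, function(s) s$at$n_candidates, 1L),
    n_significant_edges = vapply(scan, function(s) s$at$n_significant, 1L))

  sel <- max(which(trace$n_significant_edges ==
                     max(trace$n_significant_edges)))
  best <- scan[[sel]]
  structure(list(tau = best$tau, quantile = best$q, statistic = statistic,
                 method = method, alpha_adj = alpha_adj,
                 correction = correction,
                 group_summaries = summaries,
                 active_sets = best$at$active,
                 families = best$at$families,
                 scan_trace = trace),
            class = "layer_activation")
}

#' @export
print.layer_activation <- function(x, ...) {
  cat(sprintf(
    "<layer_activation: tau=%.4g (q=%.2f, %s), %d significant edge(s)>\n",
    x$tau, x$quantile, x$statistic,
    x$scan_trace$n_significant_edges[match(x$quantile,
                                           x$scan_trace$quantile)]))
  invisible(x)
}

#' Write a percolation scan trace to TSV
#'
#' @param activation A `layer_activation`.
#' @param path Output path.
#' @export
write_scan_trace <- function(activation, path) {
  utils::write.table(activation$scan_trace, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Permutation robustness check of the threshold scan
#'
#' Re-runs the percolation scan `n_perm` times with group labels permuted
#' uniformly at random, giving a per-quantile null distribution of the
#' significant-edge count and an empirical p-value
#' `(1 + #{null >= observed}) / (n_perm + 1)`.
#'
#' @inheritParams percolation_scan
#' @param n_perm Number of permutations (>= 1).
#' @param seed Optional integer seed recorded in the output.
#' @param ... Passed on to [percolation_scan()].
#' @return List of class `permutation_test`: `observed` (the unpermuted scan
#'   trace), `null` (n_perm x n_quantiles matrix of significant-edge
#'   counts), `p` (per-quantile empirical p-values), `seed`.
#' @export
permutation_threshold_test <- function(layer, labels, net,
                                       quantile_grid = default_quantile_grid(),
                                       n_perm = 50, seed = NULL, ...) {
  if (n_perm < 1)
    stop_diffnetx("n_perm must be >= 1", "diffnetx_error_bad_nperm")
  if (!is.null(seed)) set.seed(seed)
  obs <- percolation_scan(layer, labels, net, quantile_grid, ...)
  nullmat <- matrix(NA_integer_, n_perm, nrow(obs$scan_trace))
  colnames(nullmat) <- obs$scan_trace$quantile
  for (b in seq_len(n_perm)) {
    perm <- labels$assignment
    names(perm) <- sample(names(perm))
    perm_labels <- group_labels(perm)
    tr <- percolation_scan(layer, perm_labels, net, quantile_grid,
                           ...)$scan_trace
    nullmat[b, ] <- tr$n_significant_edges
  }
  pvals <- vapply(seq_len(ncol(nullmat)), function(j)
    (1 + sum(nullmat[, j] >= obs$scan_trace$n_significant_edges[j])) /
      (n_perm + 1), 1)
  structure(list(observed = obs$scan_trace, null = nullmat, p = pvals,
                 seed = seed),
            class = "permutation_test")
}
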