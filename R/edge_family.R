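# Step 2 and step 3 of the per-layer procedure: drop edges common to every
# group's active subnetwork, then test each remaining group-specific edge
# with the interaction model. Each (layer, group) pair forms one edge family,
# which is the unit of multiple-testing correction.

#' Remove edges common to all groups
#'
#' Given each group's candidate edge set, removes the intersection of all
#' groups' sets from every group: an edge absent from even one group is
#' retained wherever it is present, so only universally shared edges are
#' discarded.
#'
#' @param per_group_edge_sets Named list (one element per group, K >= 2) of
#'   character vectors of edge keys (or any comparable edge encoding).
#' @return Named list of group-specific edge sets, same order.
#' @export
remove_common_edges <- function(per_group_edge_sets) {
  if (length(per_group_edge_sets) < 2)
    stop_diffnetx("at least two groups are required",
                  "diffnetx_error_too_few_groups")
  common <- Reduce(intersect, per_group_edge_sets)
  lapply(per_group_edge_sets, function(e) setdiff(e, common))
}

# response/covariate orientation: directed source -> target puts the target
# in the response role; undirected edges use the lexicographically larger
# identifier as response (deterministic, since p-values differ by orientation)
orient_edge <- function(source, target, directed) {
  if (directed) list(u = target, v = source)
  else if (source > target) list(u = source, v = target)
  else list(u = target, v = source)
}

# Fit every candidate edge of one (layer, group) family on ALL samples (the
# interaction test needs cross-group data), correct within the family, and
# mark the differential set. `cache` memoizes fits across threshold values:
# the per-edge fit does not depend on tau, only candidacy does.
build_family <- function(keys, edge_info, values, kvec, group, layer_name,
                         nodes, method, alpha_adj, correction, min_per_group,
                         cache) {
  rows <- lapply(keys, function(key) {
    ft <- cache[[key]]
    if (is.null(ft)) {
      info <- edge_info[[key]]
      o <- orient_edge(info$source, info$target, info$directed)
      ft <- fit_interaction(values[o$u, ], values[o$v, ], kvec,
                            method = method, min_per_group = min_per_group)
      ft$u_id <- o$u
      ft$v_id <- o$v
      ft$source <- info$source
      ft$target <- info$target
      cache[[key]] <- ft
    }
    ft
  })
  if (length(keys) == 0) {
    res <- empty_edge_frame()
    return(structure(list(layer = layer_name, group = group, nodes = nodes,
                          alpha_adj = alpha_adj, correction = correction,
                          results = res, differential = res),
                     class = "edge_family"))
  }
  res <- data.frame(
    layer = layer_name, group = group,
    source = vapply(rows, `[[`, "", "source"),
    target = vapply(rows, `[[`, "", "target"),
    u_id = vapply(rows, `[[`, "", "u_id"),
    v_id = vapply(rows, `[[`, "", "v_id"),
    n = vapply(rows, function(r) as.integer(r$n_used), 1L),
    beta0 = vapply(rows, function(r) r$beta[1], 1),
    beta1 = vapply(rows, function(r) r$beta[2], 1),
    beta2 = vapply(rows, function(r) r$beta[3], 1),
    beta3 = vapply(rows, function(r) r$beta[4], 1),
    se3 = vapply(rows, `[[`, 1, "se3"),
    stat = vapply(rows, `[[`, 1, "stat"),
    df1 = vapply(rows, `[[`, 1, "df1"),
    df2 = vapply(rows, `[[`, 1, "df2"),
    p = vapply(rows, `[[`, 1, "p"),
    method = vapply(rows, `[[`, "", "method"),
    testable = vapply(rows, `[[`, TRUE, "testable"),
    reason = vapply(rows, `[[`, "", "reason"),
    stringsAsFactors = FALSE)
  # untestable edges are excluded before correction: m = testable edges only
  res$p_adj <- NA_real_
  res$p_adj[res$testable] <- adjust_pvalues(res$p[res$testable], correction)
  diff_rows <- res[res$testable & !is.na(res$p_adj) & res$p_adj < alpha_adj, ,
                   drop = FALSE]
  rownames(diff_rows) <- NULL
  structure(list(layer = layer_name, group = group, nodes = nodes,
                 alpha_adj = alpha_adj, correction = correction,
                 results = res, differential = diff_rows),
            class = "edge_family")
}

#' @export
print.edge_family <- function(x, ...) {
  cat(sprintf(
    "<edge_family layer '%s' group '%s': %d candidates, %d testable, %d differential (%s, alpha_adj=%g)>\n",
    x$layer, x$group, nrow(x$results), sum(x$results$testable),
    nrow(x$differential), x$correction, x$alpha_adj))
  invisible(x)
}

# shared driver: activation -> per-group candidates -> common-edge removal ->
# families. Returns list(families = per-group edge_family, n_candidates,
# n_significant, active = active sets).
families_at_tau <- function(layer, labels, summaries, tau, net_sub, method,
                            alpha_adj, correction, min_per_group, cache) {
  active <- activate_nodes(summaries, tau)
  edges <- net_sub$edges
  keys_all <- edge_key(edges$source, edges$target)
  edge_info <- stats::setNames(
    lapply(seq_len(nrow(edges)), function(i)
      list(source = edges$source[i], target = edges$target[i],
           directed = edges$directed[i])),
    keys_all)
  per_group <- lapply(active, function(nodes)
    keys_all[edges$source %in% nodes & edges$target %in% nodes])
  specific <- remove_common_edges(per_group)

  samples <- intersect(layer$sample_ids, names(labels$assignment))
  values <- layer$values[, samples, drop = FALSE]
  kvec <- labels$assignment[samples]

  fams <- lapply(names(specific), function(g)
    build_family(specific[[g]], edge_info, values, kvec, g, layer$layer_name,
                 active[[g]], method, alpha_adj, correction, min_per_group,
                 cache))
  names(fams) <- names(specific)
  list(families = fams,
       active = active,
       n_candidates = sum(lengths(specific)),
       n_significant = sum(vapply(fams, function(f) nrow(f$differential), 1L)))
}

#' Build per-group edge families at a fixed activation
#'
#' Runs common-edge removal and the interaction tests for every group of one
#' layer, at the activation threshold stored in `activation` (typically the
#' output of [percolation_scan()]).
#'
#' @param layer An [expression_layer()].
#' @param labels A [group_labels()].
#' @param activation A `layer_activation` from [percolation_scan()], or
#'   `NULL` to activate at `tau`.
#' @param net A [reference_network()] (restricted internally to the layer's
#'   features).
#' @param tau Explicit threshold, used when `activation` is `NULL`.
#' @param method `"ols"` or `"robust"` (K >= 3 groups always use the ANCOVA
#'   F-test).
#' @param alpha_adj Significance level applied to adjusted p-values.
#' @param correction Multiple-testing method, see [adjust_pvalues()].
#' @param statistic Summary statistic for activation when `activation` is
#'   `NULL`.
#' @param min_per_group Minimum per-group sample size for a testable edge.
#' @return Named list of `edge_family` objects, one per group. An empty
#'   family (zero candidates) is legal.
#' @export
build_edge_family <- function(layer, labels, activation = NULL, net,
                              tau = NULL, method = c("ols", "robust"),
                              alpha_adj = 0.05,
                              correction = "bonferroni",
                              statistic = "median", min_per_group = 3) {
  method <- match.arg(method)
  if (is.null(activation)) {
    if (is.null(tau))
      stop_diffnetx("supply either an activation or a tau",
                    "diffnetx_error_bad_tau")
    summaries <- compute_group_summaries(layer, labels, statistic)
  } else {
    summaries <- activation$group_summaries
    tau <- activation$tau
  }
  net_sub <- subset_to_layer(net, layer$feature_ids)
  res <- families_at_tau(layer, labels, summaries, tau, net_sub, method,
                         alpha_adj, correction, min_per_group,
                         cache = new.env(parent = emptyenv()))
  res$families
}

#' Export edge test results as a flat table
#'
#' @param families A list of `edge_family` objects (or a single one).
#' @param differential_only Keep only edges passing the family's threshold.
#' @return Data frame with one row per tested edge:
#'   `layer group source target n beta3 stat df p p_adj method`.
#' @export
edge_results_table <- function(families, differential_only = FALSE) {
  if (inherits(families, "edge_family")) families <- list(families)
  tabs <- lapply(families, function(f)
    if (differential_only) f$differential else f$results)
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  out
}
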