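# Node activation: a molecular entity is "active" in group k when its
# per-group summary expression meets the layer threshold tau (step function
# with inclusive >=). Groups are summarized and thresholded independently, so
# each group acquires its own network topology.

#' Per-group per-feature summary statistics
#'
#' Computes, for every feature and every group, the median (default) or mean
#' of the observed expression values, excluding missing cells pairwise. A
#' feature with no observed value in a group gets `NA` and is treated as
#' inactive at every threshold.
#'
#' @param layer An [expression_layer()].
#' @param labels A [group_labels()]; every group must have at least one sample
#'   present in the layer.
#' @param statistic `"median"` (default) or `"mean"`.
#' @return Numeric matrix, features x groups.
#' @export
compute_group_summaries <- function(layer, labels,
                                    statistic = c("median", "mean")) {
  stopifnot(inherits(layer, "expression_layer"),
            inherits(labels, "group_labels"))
  statistic <- match.arg(statistic)
  fun <- if (statistic == "median") stats::median else mean
  groups <- labels$groups
  out <- matrix(NA_real_, nrow(layer$values), length(groups),
                dimnames = list(layer$feature_ids, groups))
  for (g in groups) {
    ids <- intersect(names(labels$assignment)[labels$assignment == g],
                     layer$sample_ids)
    if (length(ids) == 0)
      stop_diffnetx(
        sprintf("group '%s' has no samples in layer '%s'", g, layer$layer_name),
        "diffnetx_error_empty_group")
    sub <- layer$values[, ids, drop = FALSE]
    out[, g] <- apply(sub, 1, function(r) {
      r <- r[is.finite(r)]
      if (length(r) == 0) NA_real_ else fun(r)
    })
  }
  out
}

#' Activate nodes at a threshold
#'
#' Applies the step activation function: feature v is active in group k when
#' its summary x_vk >= tau. Ties at the threshold activate; `NA` summaries
#' never activate.
#'
#' @param summaries Features x groups matrix from [compute_group_summaries()].
#' @param tau Finite activation threshold on the expression scale.
#' @return Named list (one element per group) of active feature identifiers.
#' @export
activate_nodes <- function(summaries, tau) {
  if (!is.finite(tau))
    stop_diffnetx("tau must be finite", "diffnetx_error_bad_tau")
  feats <- rownames(summaries)
  out <- lapply(colnames(summaries), function(g) {
    x <- summaries[, g]
    feats[!is.na(x) & x >= tau]
  })
  stats::setNames(out, colnames(summaries))
}
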