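#' Bootstrap stability of differential edges
#'
#' Resamples samples with replacement, stratified within groups to preserve
#' group sizes, re-runs the full pipeline (percolation threshold selection,
#' common-edge removal, interaction tests, correction) on each resample, and
#' reports how often every edge re-enters a differential set. Low
#' frequencies flag edges whose detection hinges on few samples.
#'
#' @inheritParams percolation_scan
#' @param n_boot Number of bootstrap iterations (>= 1).
#' @param seed Optional integer seed.
#' @param ... Passed to [percolation_scan()].
#' @return Data frame with columns `group`, `source`, `target`, `frequency`
#'   (selection frequency in `[0, 1]` over the `n_boot` resamples), sorted by
#'   decreasing frequency. Attribute `n_boot` records the iteration count.
#' @export
bootstrap_stability <- function(layer, labels, net, n_boot = 50, seed = NULL,
                                ...) {
  if (n_boot < 1)
    stop_diffnetx("n_boot must be >= 1", "diffnetx_error_bad_nboot")
  if (!is.null(seed)) set.seed(seed)
  samples <- intersect(layer$sample_ids, names(labels$assignment))
  by_group <- split(samples, labels$assignment[samples])
  counts <- new.env(parent = emptyenv())
  for (b in seq_len(n_boot)) {
    picked <- unlist(lapply(by_group, function(s)
      s[sample.int(length(s), length(s), replace = TRUE)]),
      use.names = FALSE)
    vals <- layer$values[, picked, drop = FALSE]
    new_ids <- sprintf("bs%04d_%s", seq_along(picked), picked)
    colnames(vals) <- new_ids
    boot_layer <- expression_layer(vals, layer$layer_name)
    boot_labels <- group_labels(stats::setNames(
      labels$assignment[picked], new_ids))
    act <- percolation_scan(boot_layer, boot_labels, net, ...)
    for (fam in act$families) {
      d <- fam$differential
      if (nrow(d) == 0) next
      keys <- paste(fam$group, edge_key(d$source, d$target), sep = .KEYSEP)
      for (key in keys)
        counts[[key]] <- (if (is.null(counts[[key]])) 0L else counts[[key]]) + 1L
    }
  }
  keys <- ls(counts)
  if (length(keys) == 0) {
    out <- data.frame(group = character(0), source = character(0),
                      target = character(0), frequency = numeric(0),
                      stringsAsFactors = FALSE)
  } else {
    parts <- do.call(rbind, strsplit(keys, .KEYSEP, fixed = TRUE))
    out <- data.frame(group = parts[, 1], source = parts[, 2],
                      target = parts[, 3],
                      frequency = vapply(keys, function(k) counts[[k]], 1L) /
                        n_boot,
                      stringsAsFactors = FALSE)
    out <- out[order(-out$frequency, out$group, out$source), ]
    rownames(out) <- NULL
  }
  attr(out, "n_boot") <- n_boot
  out
}
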