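# Supervised fit/transform feature filter. fit_filter() learns, on training
# data only, the activation threshold (by percolation) and the differential
# edges; transform_features() then derives the same single and ratio-based
# predictors for any data with the same feature columns. Because the
# transformation is a pure function of the fitted model and the row being
# transformed, the pair is safe to use inside nested cross-validation
# without leaking test information into feature selection.

#' Fit the differential-edge feature filter
#'
#' Runs the full pipeline (percolation threshold selection, common-edge
#' removal, interaction tests, correction) on the training data, ranks the
#' differential edges by ascending adjusted p-value (ties: larger absolute
#' test statistic first), and greedily admits edges in rank order until the
#' emitted feature budget is exhausted. Each admitted edge contributes one
#' ratio feature plus, when `keep_single = TRUE`, its not-yet-counted
#' endpoint features; singles and ratios count jointly toward
#' `max_features`. With `max_features = Inf` the filter sizes itself: the
#' internal percolation scan fixes how many edges are significant.
#'
#' @param x Samples x features numeric matrix (rownames = sample ids,
#'   colnames = feature ids), pre-normalized.
#' @param y Group membership for the training samples: a [group_labels()],
#'   or a vector (named, or in `rownames(x)` order) with exactly two levels.
#' @param net A [reference_network()].
#' @param max_features Cap on the number of emitted features (default
#'   unlimited).
#' @param keep_single Also emit the individual endpoint features of each
#'   admitted edge (default `TRUE`).
#' @param ... Passed to [percolation_scan()] (`quantile_grid`, `alpha_adj`,
#'   `correction`, `method`, `statistic`, ...).
#' @return Object of class `edge_filter_model`: `single_features`, `pairs`
#'   (data frame `numerator`, `denominator`, `p_adj`, `stat`), `keep_single`,
#'   `max_features`, `tau`, `quantile`. Zero differential edges yield an
#'   empty (but valid) model.
#' @export
fit_filter <- function(x, y, net, max_features = Inf, keep_single = TRUE,
                       ...) {
  x <- as.matrix(x)
  if (is.null(colnames(x)))
    stop_diffnetx("x needs feature column names",
                  "diffnetx_error_unnamed_matrix")
  if (is.null(rownames(x)))
    rownames(x) <- sprintf("sample%04d", seq_len(nrow(x)))
  labels <- if (inherits(y, "group_labels")) y else {
    yv <- as.character(y)
    if (is.null(names(yv))) names(yv) <- rownames(x)
    group_labels(yv)
  }
  if (length(labels$groups) != 2)
    stop_diffnetx("the feature filter requires exactly two groups",
                  "diffnetx_error_too_few_groups")
  if (max_features < 1)
    stop_diffnetx("max_features must be >= 1",
                  "diffnetx_error_bad_max_features")
  layer <- expression_layer(t(x), "train")
  act <- percolation_scan(layer, labels, net, ...)
  edges <- do.call(rbind, lapply(act$families, `[[`, "differential"))
  model <- structure(
    list(single_features = character(0),
         pairs = data.frame(numerator = character(0),
                            denominator = character(0),
                            p_adj = numeric(0), stat = numeric(0),
                            stringsAsFactors = FALSE),
         keep_single = isTRUE(keep_single), max_features = max_features,
         tau = act$tau, quantile = act$quantile,
         correction = act$correction, alpha_adj = act$alpha_adj),
    class = "edge_filter_model")
  if (is.null(edges) || nrow(edges) == 0) return(model)

  edges <- edges[!duplicated(edge_key(edges$source, edges$target)), ,
                 drop = FALSE]
  edges <- edges[order(edges$p_adj, -abs(edges$stat)), , drop = FALSE]
  singles <- character(0)
  taken <- 0
  admit <- logical(nrow(edges))
  for (i in seq_len(nrow(edges))) {
    new_singles <- if (keep_single)
      setdiff(c(edges$u_id[i], edges$v_id[i]), singles) else character(0)
    cost <- 1L + length(new_singles)
    if (taken + cost > max_features) break
    admit[i] <- TRUE
    singles <- c(singles, new_singles)
    taken <- taken + cost
  }
  kept <- edges[admit, , drop = FALSE]
  model$single_features <- singles
  model$pairs <- data.frame(numerator = kept$u_id,
                            denominator = kept$v_id,
                            p_adj = kept$p_adj, stat = kept$stat,
                            stringsAsFactors = FALSE)
  model
}

#' @export
print.edge_filter_model <- function(x, ...) {
  cat(sprintf(
    "<edge_filter_model: %d ratio pair(s), %d single(s), keep_single=%s, tau=%.4g (q=%.2f)>\n",
    nrow(x$pairs), length(x$single_features), x$keep_single, x$tau,
    x$quantile))
  invisible(x)
}

#' Apply a fitted feature filter to new data
#'
#' Emits, in model order, the retained single features (when
#' `keep_single = TRUE`) followed by one ratio column `A:B` = A / B per
#' admitted edge, where the numerator is the edge regression's response
#' entity. A denominator of exactly zero yields `NA` for that cell (no
#' silent infinities). The output schema depends only on the model, never on
#' the data being transformed.
#'
#' @param model An `edge_filter_model` from [fit_filter()].
#' @param x Samples x features matrix containing every feature named in the
#'   model.
#' @return Samples x derived-features numeric matrix (zero columns for an
#'   empty model).
#' @export
transform_features <- function(model, x) {
  stopifnot(inherits(model, "edge_filter_model"))
  x <- as.matrix(x)
  need <- unique(c(model$single_features,
                   model$pairs$numerator, model$pairs$denominator))
  missing <- setdiff(need, colnames(x))
  if (length(missing) > 0)
    stop_diffnetx(sprintf("features absent from x: %s",
                          paste(missing, collapse = ", ")),
                  "diffnetx_error_missing_feature")
  cols <- list()
  if (model$keep_single && length(model$single_features) > 0) {
    singles <- x[, model$single_features, drop = FALSE]
    cols <- c(cols, list(singles))
  }
  if (nrow(model$pairs) > 0) {
    ratios <- vapply(seq_len(nrow(model$pairs)), function(i) {
      num <- x[, model$pairs$numerator[i]]
      den <- x[, model$pairs$denominator[i]]
      out <- num / den
      out[!is.na(den) & den == 0] <- NA_real_
      out
    }, numeric(nrow(x)))
    ratios <- matrix(ratios, nrow = nrow(x),
                     dimnames = list(rownames(x),
                                     paste(model$pairs$numerator,
                                           model$pairs$denominator,
                                           sep = ":")))
    cols <- c(cols, list(ratios))
  }
  if (length(cols) == 0)
    return(matrix(numeric(0), nrow = nrow(x), ncol = 0,
                  dimnames = list(rownames(x), character(0))))
  do.call(cbind, cols)
}

#' @rdname transform_features
#' @param object An `edge_filter_model`.
#' @param newdata Samples x features matrix.
#' @param ... Ignored.
#' @export
predict.edge_filter_model <- function(object, newdata, ...) {
  transform_features(object, newdata)
}

#' Serialize / restore a feature filter model
#'
#' Versioned JSON (`diffnetx-filter/1`), round-trippable.
#'
#' @param model An `edge_filter_model`.
#' @param path File path.
#' @return `path` (write) or the restored model (read).
#' @export
write_filter_model <- function(model, path) {
  obj <- c(list(schema = "diffnetx-filter/1"), unclass(model))
  # JSON has no Inf: encode an unlimited budget as -1
  obj$max_features <- if (is.finite(model$max_features))
    model$max_features else -1
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_filter_model
#' @export
read_filter_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "diffnetx-filter/1"))
    stop_diffnetx("unrecognized filter model schema",
                  "diffnetx_error_bad_schema")
  pairs <- as.data.frame(obj$pairs, stringsAsFactors = FALSE)
  if (nrow(pairs) == 0)
    pairs <- data.frame(numerator = character(0), denominator = character(0),
                        p_adj = numeric(0), stat = numeric(0),
                        stringsAsFactors = FALSE)
  structure(list(single_features = as.character(unlist(obj$single_features)),
                 pairs = pairs, keep_single = isTRUE(obj$keep_single),
                 max_features = if (is.null(obj$max_features) ||
                                    obj$max_features < 0) Inf
                                else obj$max_features,
                 tau = obj$tau, quantile = obj$quantile,
                 correction = obj$correction, alpha_adj = obj$alpha_adj),
            class = "edge_filter_model")
}
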