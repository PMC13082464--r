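# Prior knowledge network G = (V, E): literature-curated molecular
# interactions supplied as a tabular edge list. Direction, when present, is
# orientation metadata (it fixes the response/covariate roles of the edge
# regression and is displayed on export) but never enters any statistic.

detect_delimiter <- function(path) {
  first <- readLines(path, n = 1L)
  counts <- c("\t" = lengths(regmatches(first, gregexpr("\t", first, fixed = TRUE))),
              "," = lengths(regmatches(first, gregexpr(",", first, fixed = TRUE))),
              ";" = lengths(regmatches(first, gregexpr(";", first, fixed = TRUE))))
  if (all(counts == 0)) return("\t")
  # ties resolve to tab, the canonical dialect (names() order is preserved)
  names(counts)[which.max(counts)]
}

new_reference_network <- function(edges) {
  rownames(edges) <- NULL
  vertices <- sort(unique(c(edges$source, edges$target)))
  structure(list(edges = edges, vertices = vertices),
            class = "reference_network")
}

#' Construct a reference network from edge vectors
#'
#' Self-loops are dropped (with a warning giving the count) and duplicate
#' unordered endpoint pairs are collapsed, keeping the first occurrence's
#' direction flag. Identifier case is preserved and matching is exact.
#'
#' @param source,target Character vectors of endpoint identifiers.
#' @param directed Logical vector (recycled): is the edge source -> target?
#' @param provenance Optional character vector of free-text annotations.
#' @return Object of class `reference_network` with `edges` (data frame with
#'   columns source, target, directed, provenance) and `vertices` (sorted
#'   union of endpoints).
#' @examples
#' reference_network(c("A", "B"), c("B", "C"))
#' @export
reference_network <- function(source, target, directed = FALSE,
                              provenance = NA_character_) {
  source <- trimws(as.character(source))
  target <- trimws(as.character(target))
  n <- length(source)
  if (length(target) != n)
    stop_diffnetx("source and target must have equal length",
                  "diffnetx_error_bad_columns")
  edges <- data.frame(source = source, target = target,
                      directed = rep_len(as.logical(directed), n),
                      provenance = rep_len(as.character(provenance), n),
                      stringsAsFactors = FALSE)
  bad <- !nzchar(edges$source) | !nzchar(edges$target)
  if (any(bad)) {
    warning(sprintf("dropped %d edge(s) with empty identifiers", sum(bad)))
    edges <- edges[!bad, , drop = FALSE]
  }
  loops <- edges$source == edges$target
  if (any(loops)) {
    warning(sprintf("dropped %d self-loop(s)", sum(loops)))
    edges <- edges[!loops, , drop = FALSE]
  }
  edges <- edges[!duplicated(edge_key(edges$source, edges$target)), ,
                 drop = FALSE]
  new_reference_network(edges)
}

#' @export
print.reference_network <- function(x, ...) {
  cat(sprintf("<reference_network: %d vertices, %d edges (%d directed)>\n",
              length(x$vertices), nrow(x$edges), sum(x$edges$directed)))
  invisible(x)
}

#' Load a reference network from a delimited edge list
#'
#' The file must have a header and at least two columns (source, target); an
#' optional third column marks direction (logical, or strings such as
#' "directed"/"undirected", or 0/1). Delimiter is auto-detected among tab,
#' comma and semicolon.
#'
#' @param path Path to the edge-list file.
#' @param has_direction `NA` (default) to use the third column when present,
#'   otherwise `TRUE`/`FALSE` to force the interpretation.
#' @return A [reference_network()].
#' @export
load_reference_network <- function(path, has_direction = NA) {
  if (!file.exists(path))
    stop_diffnetx(sprintf("file not found: %s", path),
                  "diffnetx_error_missing_file")
  sep <- detect_delimiter(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "\"", comment.char = "")
  if (ncol(df) < 2)
    stop_diffnetx("edge list needs at least source and target columns",
                  "diffnetx_error_bad_columns")
  use_dir <- if (is.na(has_direction)) ncol(df) >= 3 else isTRUE(has_direction)
  directed <- if (use_dir && ncol(df) >= 3) parse_direction(df[[3]]) else FALSE
  net <- reference_network(df[[1]], df[[2]], directed = directed)
  if (nrow(net$edges) == 0)
    stop_diffnetx("network is empty after filtering self-loops/duplicates",
                  "diffnetx_error_empty_network")
  net
}

parse_direction <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(x != 0)
  x <- tolower(trimws(as.character(x)))
  x %in% c("true", "t", "1", "yes", "directed", "->")
}

#' Restrict a reference network to measured features
#'
#' Keeps only edges whose both endpoints belong to `feature_ids` (the entities
#' measured in one omic layer). The result may be empty.
#'
#' @param net A [reference_network()].
#' @param feature_ids Non-empty character vector of identifiers.
#' @return A `reference_network` over the retained edges.
#' @export
subset_to_layer <- function(net, feature_ids) {
  stopifnot(inherits(net, "reference_network"))
  if (length(feature_ids) == 0)
    stop_diffnetx("feature_ids must be non-empty",
                  "diffnetx_error_empty_feature_set")
  keep <- net$edges$source %in% feature_ids & net$edges$target %in% feature_ids
  new_reference_network(net$edges[keep, , drop = FALSE])
}

#' Load a cross-layer identifier mapping
#'
#' A many-to-many correspondence table aligning identifier namespaces across
#' omic layers (e.g. gene symbol to protein identifier). Expected columns:
#' `layer_a`, `id_a`, `layer_b`, `id_b`.
#'
#' @param path Path to the mapping file (delimiter auto-detected).
#' @return Data frame of class `layer_mapping`.
#' @export
load_layer_mapping <- function(path) {
  if (!file.exists(path))
    stop_diffnetx(sprintf("file not found: %s", path),
                  "diffnetx_error_missing_file")
  sep <- detect_delimiter(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("layer_a", "id_a", "layer_b", "id_b")
  if (!all(need %in% names(df)))
    stop_diffnetx("mapping needs columns layer_a, id_a, layer_b, id_b",
                  "diffnetx_error_bad_columns")
  df <- df[need]
  df[] <- lapply(df, function(col) trimws(as.character(col)))
  class(df) <- c("layer_mapping", class(df))
  df
}

#' Build a cross-layer identifier mapping in code
#'
#' @param layer_a,id_a,layer_b,id_b Character vectors of equal length.
#' @return Data frame of class `layer_mapping`.
#' @export
layer_mapping <- function(layer_a, id_a, layer_b, id_b) {
  df <- data.frame(layer_a = as.character(layer_a), id_a = as.character(id_a),
                   layer_b = as.character(layer_b), id_b = as.character(id_b),
                   stringsAsFactors = FALSE)
  class(df) <- c("layer_mapping", class(df))
  df
}
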