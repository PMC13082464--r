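#' Construct an expression layer
#'
#' An expression layer holds one omic data modality (RNA-seq, proteomics,
#' O-link, ...) as a feature-by-sample numeric matrix. Values must already be
#' normalized and variance-stabilized (e.g. log2 or VST for RNA-seq): the
#' package performs no normalization, transformation, or imputation. Missing
#' values are permitted and are excluded pairwise downstream.
#'
#' @param values Numeric matrix, features in rows, samples in columns, with
#'   unique rownames (feature identifiers) and colnames (sample identifiers).
#' @param layer_name Single string labelling the omic layer.
#' @return An object of class `expression_layer` with elements `values`,
#'   `feature_ids`, `sample_ids`, `layer_name`.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(c("A", "B", "C"), paste0("s", 1:4)))
#' expression_layer(m, "rna")
#' @export
expression_layer <- function(values, layer_name = "layer1") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_diffnetx("expression layer matrix must have row and column names",
                  "diffnetx_error_unnamed_matrix")
  if (anyDuplicated(rownames(values)))
    stop_diffnetx("duplicated feature identifiers in layer",
                  "diffnetx_error_duplicate_ids")
  if (anyDuplicated(colnames(values)))
    stop_diffnetx("duplicated sample identifiers in layer",
                  "diffnetx_error_duplicate_ids")
  structure(
    list(values = values,
         feature_ids = rownames(values),
         sample_ids = colnames(values),
         layer_name = as.character(layer_name)[1]),
    class = "expression_layer")
}

#' @export
print.expression_layer <- function(x, ...) {
  cat(sprintf("<expression_layer '%s': %d features x %d samples, %d NA cells>\n",
              x$layer_name, nrow(x$values), ncol(x$values),
              sum(is.na(x$values))))
  invisible(x)
}

#' Read an expression layer from delimited text
#'
#' Features are rows; the first column holds feature identifiers and the
#' remaining columns one sample each. The delimiter is auto-detected among
#' tab, comma and semicolon (tab is the canonical dialect).
#'
#' @param path Path to a delimited text file.
#' @param layer_name Layer label; defaults to the file name without extension.
#' @return An [expression_layer()].
#' @export
read_expression_layer <- function(path, layer_name = NULL) {
  if (!file.exists(path))
    stop_diffnetx(sprintf("file not found: %s", path),
                  "diffnetx_error_missing_file")
  sep <- detect_delimiter(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "\"", comment.char = "")
  if (ncol(df) < 2)
    stop_diffnetx("expression file needs an identifier column plus >=1 sample column",
                  "diffnetx_error_bad_columns")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- trimws(as.character(df[[1]]))
  if (is.null(layer_name))
    layer_name <- sub("\\.[^.]*$", "", basename(path))
  expression_layer(m, layer_name)
}

#' Construct group labels
#'
#' Assigns each sample to one of K >= 2 experimental groups or conditions.
#'
#' @param assignment Named character vector: names are sample identifiers,
#'   values are group labels. An unnamed vector may be supplied together with
#'   `sample_ids`.
#' @param sample_ids Optional character vector of sample identifiers matching
#'   `assignment` by position.
#' @return Object of class `group_labels` with elements `assignment` (named
#'   character) and `groups` (sorted distinct labels).
#' @examples
#' group_labels(c(s1 = "resp", s2 = "nonresp", s3 = "resp"))
#' @export
group_labels <- function(assignment, sample_ids = NULL) {
  assignment <- vapply(assignment, as.character, character(1))
  if (!is.null(sample_ids)) names(assignment) <- as.character(sample_ids)
  if (is.null(names(assignment)) || any(!nzchar(names(assignment))))
    stop_diffnetx("every sample needs an identifier",
                  "diffnetx_error_unnamed_samples")
  if (anyDuplicated(names(assignment)))
    stop_diffnetx("duplicated sample identifiers in labels",
                  "diffnetx_error_duplicate_ids")
  groups <- sort(unique(assignment))
  if (length(groups) < 2)
    stop_diffnetx("at least two groups are required (K >= 2)",
                  "diffnetx_error_too_few_groups")
  structure(list(assignment = assignment, groups = groups),
            class = "group_labels")
}

#' @export
print.group_labels <- function(x, ...) {
  cat(sprintf("<group_labels: %d samples in %d groups (%s)>\n",
              length(x$assignment), length(x$groups),
              paste(x$groups, collapse = ", ")))
  invisible(x)
}

#' Read sample metadata
#'
#' Expects columns `sample_id` and `group` (extra columns are ignored).
#'
#' @param path Path to a delimited text file.
#' @return A [group_labels()] object.
#' @export
read_group_labels <- function(path) {
  if (!file.exists(path))
    stop_diffnetx(sprintf("file not found: %s", path),
                  "diffnetx_error_missing_file")
  sep <- detect_delimiter(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(df)))
    stop_diffnetx("metadata needs columns 'sample_id' and 'group'",
                  "diffnetx_error_bad_columns")
  group_labels(stats::setNames(trimws(as.character(df$group)),
                               trimws(as.character(df$sample_id))))
}
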