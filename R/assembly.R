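# Multi-omic assembly: per-layer differential graphs are derived on their
# own samples and stacked at the final stage. Cross-layer identifier
# correspondences become a distinct "correspondence" link class; nodes are
# never merged, so each layer's statistics stay attributable to the samples
# that produced them.

#' Assemble per-layer differential graphs into one multi-omic network
#'
#' @param per_layer Named list (names = layer labels) of `edge_family`
#'   objects for one group, as produced by [percolation_scan()] (element
#'   `families[[group]]`) or [build_edge_family()].
#' @param group Group label of the assembled network.
#' @param mapping Optional [layer_mapping()] aligning identifiers across
#'   layers; pairs whose identifiers are not active nodes of the respective
#'   layers are skipped with one warning giving the count.
#' @return Object of class `differential_network`: `group`, `layers` (per
#'   layer: `nodes`, `edges` data frame with the interaction statistics) and
#'   `alignment` (data frame of cross-layer correspondence links).
#' @export
integrate_layers <- function(per_layer, group, mapping = NULL) {
  if (length(per_layer) == 0)
    stop_diffnetx("at least one layer is required",
                  "diffnetx_error_no_layers")
  if (is.null(names(per_layer)) || any(!nzchar(names(per_layer))))
    names(per_layer) <- vapply(per_layer, `[[`, "", "layer")
  layers <- lapply(per_layer, function(f) {
    stopifnot(inherits(f, "edge_family"))
    list(nodes = f$nodes, edges = f$differential)
  })
  alignment <- data.frame(layer_a = character(0), id_a = character(0),
                          layer_b = character(0), id_b = character(0),
                          stringsAsFactors = FALSE)
  if (!is.null(mapping)) {
    keep <- vapply(seq_len(nrow(mapping)), function(i) {
      a <- mapping$layer_a[i]; b <- mapping$layer_b[i]
      a %in% names(layers) && b %in% names(layers) &&
        mapping$id_a[i] %in% layers[[a]]$nodes &&
        mapping$id_b[i] %in% layers[[b]]$nodes
    }, TRUE)
    if (any(!keep))
      warning(sprintf(
        "skipped %d mapping pair(s) referencing identifiers not in the network",
        sum(!keep)))
    alignment <- as.data.frame(mapping[keep, , drop = FALSE])
    rownames(alignment) <- NULL
    class(alignment) <- "data.frame"
  }
  structure(list(group = group, layers = layers, alignment = alignment),
            class = "differential_network")
}

#' @export
print.differential_network <- function(x, ...) {
  ne <- sum(vapply(x$layers, function(l) nrow(l$edges), 1L))
  nn <- length(unique(unlist(lapply(names(x$layers), function(nm)
    paste(nm, x$layers[[nm]]$nodes, sep = ":")))))
  cat(sprintf(
    "<differential_network group '%s': %d layer(s), %d nodes, %d differential edge(s), %d correspondence link(s)>\n",
    x$group, length(x$layers), nn, ne, nrow(x$alignment)))
  invisible(x)
}

n_network_edges <- function(net) {
  sum(vapply(net$layers, function(l) nrow(l$edges), 1L))
}

#' Run the full pipeline over several omic layers
#'
#' Convenience driver: per layer, selects the activation threshold by
#' [percolation_scan()] and derives the edge families; then assembles one
#' [integrate_layers()] network per group.
#'
#' @param layers Named list of [expression_layer()] objects.
#' @param labels A [group_labels()] (layers may cover different sample
#'   subsets; no cross-omic sample matching is required).
#' @param net A [reference_network()].
#' @param mapping Optional [layer_mapping()].
#' @param ... Passed to [percolation_scan()].
#' @return List with `networks` (one `differential_network` per group) and
#'   `activations` (one `layer_activation` per layer).
#' @export
diff_networks <- function(layers, labels, net, mapping = NULL, ...) {
  if (is.null(names(layers)))
    names(layers) <- vapply(layers, `[[`, "", "layer_name")
  activations <- lapply(layers, function(l)
    percolation_scan(l, labels, net, ...))
  networks <- lapply(labels$groups, function(g) {
    per_layer <- lapply(activations, function(a) a$families[[g]])
    integrate_layers(per_layer, g, mapping)
  })
  names(networks) <- labels$groups
  list(networks = networks, activations = activations)
}

# ---------------------------------------------------------------- exports --

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

# -log10(p_adj), capped so that underflowing p-values stay finite
edge_thickness <- function(p_adj, cap = 10) {
  pmin(cap, -log10(pmax(p_adj, .Machine$double.xmin)))
}

#' Export a differential network
#'
#' Formats: `"tsv"` (flat edge table), `"json"` (full structure,
#' round-trippable via [import_network_json()], schema
#' `diffnetx-network/1`), `"graphml"` (nodes carry layer and group
#' attributes; edges carry layer, p, p_adj, beta3 and a thickness proxy
#' `-log10(p_adj)` capped at 10; cross-layer correspondence links get
#' `class = "correspondence"`). TSV and GraphML require a non-empty network;
#' an empty network may be written as JSON.
#'
#' @param net A `differential_network`.
#' @param path Output file path.
#' @param format One of `"tsv"`, `"json"`, `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("tsv", "json", "graphml")) {
  stopifnot(inherits(net, "differential_network"))
  format <- match.arg(format)
  if (format %in% c("tsv", "graphml") && n_network_edges(net) == 0)
    stop_diffnetx("cannot export an empty network to tsv/graphml",
                  "diffnetx_error_empty_network")
  switch(format,
         tsv = export_network_tsv(net, path),
         json = export_network_json(net, path),
         graphml = export_network_graphml(net, path))
  invisible(path)
}

export_network_tsv <- function(net, path) {
  cols <- c("layer", "group", "source", "target", "n", "beta3", "stat",
            "df2", "p", "p_adj", "method")
  tab <- do.call(rbind, lapply(net$layers, function(l) l$edges[, cols]))
  names(tab)[names(tab) == "df2"] <- "df"
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

export_network_json <- function(net, path) {
  obj <- list(schema = "diffnetx-network/1",
              group = net$group,
              layers = lapply(net$layers, function(l)
                list(nodes = l$nodes, edges = l$edges)),
              alignment = net$alignment)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null")
}

#' Import a differential network from its JSON export
#'
#' @param path Path to a file written by [export_network()] with
#'   `format = "json"`.
#' @return A `differential_network`.
#' @export
import_network_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "diffnetx-network/1"))
    stop_diffnetx("unrecognized network JSON schema",
                  "diffnetx_error_bad_schema")
  proto <- empty_edge_frame()
  coercers <- list(character = as.character, numeric = as.numeric,
                   integer = as.integer, logical = as.logical)
  layers <- lapply(obj$layers, function(l) {
    edges <- as.data.frame(l$edges, stringsAsFactors = FALSE)
    if (nrow(edges) == 0) edges <- proto
    # JSON null columns come back logical; restore the documented types
    for (nm in intersect(names(edges), names(proto)))
      edges[[nm]] <- coercers[[class(proto[[nm]])[1]]](edges[[nm]])
    list(nodes = as.character(unlist(l$nodes)), edges = edges)
  })
  alignment <- as.data.frame(obj$alignment, stringsAsFactors = FALSE)
  if (nrow(alignment) == 0)
    alignment <- data.frame(layer_a = character(0), id_a = character(0),
                            layer_b = character(0), id_b = character(0),
                            stringsAsFactors = FALSE)
  structure(list(group = obj$group, layers = layers, alignment = alignment),
            class = "differential_network")
}

empty_edge_frame <- function() {
  data.frame(layer = character(0), group = character(0),
             source = character(0), target = character(0),
             u_id = character(0), v_id = character(0), n = integer(0),
             beta0 = numeric(0), beta1 = numeric(0), beta2 = numeric(0),
             beta3 = numeric(0), se3 = numeric(0), stat = numeric(0),
             df1 = numeric(0), df2 = numeric(0), p = numeric(0),
             method = character(0), testable = logical(0),
             reason = character(0), p_adj = numeric(0),
             stringsAsFactors = FALSE)
}

export_network_graphml <- function(net, path) {
  node_id <- function(layer, id) paste0(layer, "::", id)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="d_name" for="node" attr.name="name" attr.type="string"/>',
    '  <key id="d_layer" for="node" attr.name="layer" attr.type="string"/>',
    '  <key id="d_group" for="node" attr.name="group" attr.type="string"/>',
    '  <key id="e_layer" for="edge" attr.name="layer" attr.type="string"/>',
    '  <key id="e_class" for="edge" attr.name="class" attr.type="string"/>',
    '  <key id="e_p" for="edge" attr.name="p" attr.type="double"/>',
    '  <key id="e_padj" for="edge" attr.name="p_adj" attr.type="double"/>',
    '  <key id="e_beta3" for="edge" attr.name="beta3" attr.type="double"/>',
    '  <key id="e_thickness" for="edge" attr.name="thickness" attr.type="double"/>',
    sprintf('  <graph id="%s" edgedefault="undirected">',
            xml_escape(net$group)))
  for (nm in names(net$layers)) {
    l <- net$layers[[nm]]
    used <- unique(c(l$edges$source, l$edges$target))
    for (v in used) {
      lines <- c(lines, sprintf(
        '    <node id="%s"><data key="d_name">%s</data><data key="d_layer">%s</data><data key="d_group">%s</data></node>',
        xml_escape(node_id(nm, v)), xml_escape(v), xml_escape(nm),
        xml_escape(net$group)))
    }
    if (nrow(l$edges) > 0) {
      th <- edge_thickness(l$edges$p_adj)
      for (i in seq_len(nrow(l$edges))) {
        lines <- c(lines, sprintf(
          paste0('    <edge source="%s" target="%s">',
                 '<data key="e_layer">%s</data>',
                 '<data key="e_class">differential</data>',
                 '<data key="e_p">%.17g</data>',
                 '<data key="e_padj">%.17g</data>',
                 '<data key="e_beta3">%.17g</data>',
                 '<data key="e_thickness">%.17g</data></edge>'),
          xml_escape(node_id(nm, l$edges$source[i])),
          xml_escape(node_id(nm, l$edges$target[i])),
          xml_escape(nm), l$edges$p[i], l$edges$p_adj[i],
          l$edges$beta3[i], th[i]))
      }
    }
  }
  if (nrow(net$alignment) > 0) {
    for (i in seq_len(nrow(net$alignment))) {
      a <- net$alignment[i, ]
      ids <- c(node_id(a$layer_a, a$id_a), node_id(a$layer_b, a$id_b))
      # correspondence links may touch nodes without differential edges
      for (j in 1:2) {
        nm <- c(a$layer_a, a$layer_b)[j]; v <- c(a$id_a, a$id_b)[j]
        if (!any(grepl(sprintf('node id="%s"', xml_escape(ids[j])), lines,
                       fixed = TRUE)))
          lines <- c(lines, sprintf(
            '    <node id="%s"><data key="d_name">%s</data><data key="d_layer">%s</data><data key="d_group">%s</data></node>',
            xml_escape(ids[j]), xml_escape(v), xml_escape(nm),
            xml_escape(net$group)))
      }
      lines <- c(lines, sprintf(
        '    <edge source="%s" target="%s"><data key="e_class">correspondence</data></edge>',
        xml_escape(ids[1]), xml_escape(ids[2])))
    }
  }
  lines <- c(lines, "  </graph>", "</graphml>")
  writeLines(lines, path)
}

#' Structural validation of a GraphML file
#'
#' Checks the document is well-formed XML in the GraphML namespace, that
#' every `data` element references a declared `key` for its domain, and that
#' every edge endpoint refers to a declared node.
#'
#' @param path Path to a GraphML file.
#' @return `TRUE` invisibly; otherwise an error describing the violation.
#' @export
validate_graphml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns(doc)
  root_ns <- xml2::xml_ns(doc)[["d1"]]
  if (xml2::xml_name(doc) != "graphml" ||
      !identical(root_ns, "http://graphml.graphdrawing.org/xmlns"))
    stop_diffnetx("root element is not GraphML",
                  "diffnetx_error_invalid_graphml")
  keys <- xml2::xml_find_all(doc, ".//d1:key", ns)
  key_ids <- xml2::xml_attr(keys, "id")
  data_keys <- xml2::xml_attr(xml2::xml_find_all(doc, ".//d1:data", ns),
                              "key")
  if (!all(data_keys %in% key_ids))
    stop_diffnetx("data element references an undeclared key",
                  "diffnetx_error_invalid_graphml")
  node_ids <- xml2::xml_attr(xml2::xml_find_all(doc, ".//d1:node", ns), "id")
  if (anyDuplicated(node_ids))
    stop_diffnetx("duplicated node ids", "diffnetx_error_invalid_graphml")
  edges <- xml2::xml_find_all(doc, ".//d1:edge", ns)
  ends <- c(xml2::xml_attr(edges, "source"), xml2::xml_attr(edges, "target"))
  if (!all(ends %in% node_ids))
    stop_diffnetx("edge endpoint refers to an undeclared node",
                  "diffnetx_error_invalid_graphml")
  invisible(TRUE)
}
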