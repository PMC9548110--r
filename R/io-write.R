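# Graph serialisation: Graphia/BioLayout ".layout", GraphML, edge TSV.
#
# The ".layout" dialect written here is the edge + node-class subset of the
# legacy BioLayout schema:
#   edge line:        "<node_a>" "<node_b>" <weight>
#   annotation line:  //NODECLASS "<node>" "<value>" "<attribute_name>"
# UTF-8, LF line endings; weights always carry a decimal point so they can
# never be mistaken for a third node token. Because the full modern grammar
# is not published, the writer is paired with read_layout() and the pair is
# held to a round-trip identity.

fmt_weight <- function(w) {
  s <- vapply(w, function(x) format(x, digits = 15, scientific = FALSE,
                                    trim = TRUE), character(1))
  ifelse(grepl(".", s, fixed = TRUE), s, paste0(s, ".0"))
}

# Normalise the annotation argument to a data.frame(node, value, attribute).
normalize_annotations <- function(annotations, nodes) {
  if (is.null(annotations)) {
    return(data.frame(node = character(), value = character(),
                      attribute = character(), stringsAsFactors = FALSE))
  }
  if (inherits(annotations, "cluster_assignment")) {
    annotations <- list(cluster = annotations)
  }
  if (inherits(annotations, "metadata_table")) {
    md <- annotations
    annotations <- lapply(setdiff(colnames(md), "genome_id"),
                          function(a) metadata_attribute(md, a))
    names(annotations) <- setdiff(colnames(md), "genome_id")
  }
  if (!is.list(annotations) || is.null(names(annotations))) {
    stop("annotations must be a metadata_table, a cluster_assignment, ",
         "or a named list of named vectors")
  }
  rows <- lapply(names(annotations), function(a) {
    v <- annotations[[a]]
    v <- v[names(v) %in% nodes & !is.na(v)]
    if (!length(v)) return(NULL)
    data.frame(node = names(v), value = as.character(v), attribute = a,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(node = character(), value = character(),
                                      attribute = character(),
                                      stringsAsFactors = FALSE)
  out
}

#' Write a graph in Graphia ".layout" format
#'
#' One edge per line as a quoted node pair plus numeric weight, then one
#' `//NODECLASS` line per (node, attribute) pair. Node attributes already on
#' the graph are written alongside any supplied annotations. Isolated,
#' unannotated nodes are kept restorable through a reserved `_isolated`
#' node class that [read_layout()] strips again.
#'
#' @param graph weighted igraph; must be non-empty.
#' @param path output file.
#' @param annotations optional `metadata_table`, `cluster_assignment`, or
#'   named list of named vectors (attribute -> node -> value).
#' @param include_node_attrs also serialise the graph's own node attributes
#'   (default TRUE).
#' @return the path, invisibly.
#' @export
write_layout <- function(graph, path, annotations = NULL,
                         include_node_attrs = TRUE) {
  if (igraph::vcount(graph) == 0) stop("refusing to write an empty graph")
  nodes <- igraph::V(graph)$name
  if (any(grepl("\"", nodes, fixed = TRUE))) {
    stop("node names must not contain the quote character: ",
         nodes[grepl("\"", nodes, fixed = TRUE)][1])
  }
  ann <- normalize_annotations(annotations, nodes)
  if (include_node_attrs) {
    for (a in setdiff(igraph::vertex_attr_names(graph),
                      c("name", "member_genes"))) {
      v <- igraph::vertex_attr(graph, a)
      keep <- !is.na(v)
      if (any(keep)) {
        ann <- rbind(ann, data.frame(node = nodes[keep],
                                     value = as.character(v[keep]),
                                     attribute = a, stringsAsFactors = FALSE))
      }
    }
  }
  if (any(grepl("\"", c(ann$value, ann$attribute), fixed = TRUE))) {
    stop("annotation values must not contain the quote character")
  }
  et <- graph_edge_table(graph)
  edge_lines <- sprintf("\"%s\" \"%s\" %s", et$from, et$to,
                        fmt_weight(et$weight))
  covered <- unique(c(et$from, et$to, ann$node))
  bare <- setdiff(nodes, covered)
  if (length(bare)) {
    ann <- rbind(ann, data.frame(node = bare, value = "true",
                                 attribute = "_isolated",
                                 stringsAsFactors = FALSE))
  }
  ann <- ann[order(ann$attribute, ann$node), , drop = FALSE]
  class_lines <- sprintf("//NODECLASS \"%s\" \"%s\" \"%s\"",
                         ann$node, ann$value, ann$attribute)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(edge_lines, class_lines), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' @rdname write_layout
#' @return for `read_layout`, the reconstructed weighted igraph with node
#'   class annotations restored as node attributes.
#' @export
read_layout <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  is_class <- startsWith(lines, "//NODECLASS")
  edge_re <- '^"([^"]*)" "([^"]*)" ([-0-9.eE+]+)\\s*$'
  class_re <- '^//NODECLASS "([^"]*)" "([^"]*)" "([^"]*)"\\s*$'
  edge_m <- regmatches(lines[!is_class], regexec(edge_re, lines[!is_class]))
  if (any(lengths(edge_m) != 4)) {
    stop("unparseable .layout edge line: ",
         lines[!is_class][which(lengths(edge_m) != 4)[1]])
  }
  class_m <- regmatches(lines[is_class], regexec(class_re, lines[is_class]))
  if (any(lengths(class_m) != 4)) {
    stop("unparseable .layout NODECLASS line: ",
         lines[is_class][which(lengths(class_m) != 4)[1]])
  }
  edges <- data.frame(
    from = vapply(edge_m, `[`, character(1), 2),
    to = vapply(edge_m, `[`, character(1), 3),
    weight = as.numeric(vapply(edge_m, `[`, character(1), 4)),
    stringsAsFactors = FALSE)
  ann <- data.frame(
    node = vapply(class_m, `[`, character(1), 2),
    value = vapply(class_m, `[`, character(1), 3),
    attribute = vapply(class_m, `[`, character(1), 4),
    stringsAsFactors = FALSE)
  nodes <- unique(c(edges$from, edges$to, ann$node))
  g <- weighted_graph(edges, nodes = nodes)
  for (a in setdiff(unique(ann$attribute), "_isolated")) {
    sub <- ann[ann$attribute == a, ]
    v <- rep(NA_character_, length(nodes))
    v[match(sub$node, nodes)] <- sub$value
    # restore numeric attributes (e.g. gene frequencies) as numbers
    num <- suppressWarnings(as.numeric(v[!is.na(v)]))
    if (!anyNA(num)) {
      vn <- rep(NA_real_, length(nodes))
      vn[!is.na(v)] <- num
      g <- igraph::set_vertex_attr(g, a, value = vn)
    } else {
      g <- igraph::set_vertex_attr(g, a, value = v)
    }
  }
  g
}

#' Export a graph to a standard format
#'
#' @param graph weighted igraph; must be non-empty (over-filtered upstream
#'   graphs surface as an error rather than an empty file).
#' @param path output file.
#' @param format `"graphml"` (lossless for node/edge attributes),
#'   `"edge_tsv"` (header `source<TAB>target<TAB>weight`; a `<path>.nodes.tsv`
#'   twin carries node attributes when present), or `"layout"`.
#' @param ... passed on to [write_layout()] for `format = "layout"`.
#' @return the path, invisibly.
#' @export
export_graph <- function(graph, path, format = c("graphml", "edge_tsv",
                                                 "layout"), ...) {
  format <- match.arg(format)
  if (igraph::vcount(graph) == 0) stop("refusing to export an empty graph")
  if (format == "graphml") {
    g <- graph
    if (!is.null(igraph::graph_attr(g, "transform_log"))) {
      g <- igraph::delete_graph_attr(g, "transform_log")  # not serialisable
    }
    if ("member_genes" %in% igraph::vertex_attr_names(g)) {
      members <- vapply(igraph::V(g)$member_genes,
                        function(x) paste(x, collapse = ";"), character(1))
      g <- igraph::delete_vertex_attr(g, "member_genes")
      g <- igraph::set_vertex_attr(g, "member_genes", value = members)
    }
    igraph::write_graph(g, path, format = "graphml")
  } else if (format == "edge_tsv") {
    et <- graph_edge_table(graph)
    colnames(et) <- c("source", "target", "weight")
    utils::write.table(et, path, sep = "\t", quote = FALSE, row.names = FALSE)
    attrs <- setdiff(igraph::vertex_attr_names(graph),
                     c("name", "member_genes"))
    if (length(attrs)) {
      nt <- data.frame(node = igraph::V(graph)$name, stringsAsFactors = FALSE)
      for (a in attrs) nt[[a]] <- igraph::vertex_attr(graph, a)
      utils::write.table(nt, paste0(path, ".nodes.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  } else {
    write_layout(graph, path, ...)
  }
  invisible(path)
}

#' Read a GraphML file written by [export_graph()]
#'
#' @param path input file.
#' @return weighted igraph.
#' @export
read_graphml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  g <- igraph::read_graph(path, format = "graphml")
  # igraph surfaces the XML node ids ("n0", "n1", ...) as an "id" vertex
  # attribute on read; the writer never emits one, so drop it to keep
  # write -> read an identity
  if ("id" %in% igraph::vertex_attr_names(g)) {
    g <- igraph::delete_vertex_attr(g, "id")
  }
  g
}
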