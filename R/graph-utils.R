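# Shared helpers around the igraph-backed weighted-graph container.
#
# All three network types (genome-genome, gene-gene, synteny) are plain
# undirected igraph objects with a positive `weight` edge attribute and
# arbitrary node attributes; no self-loops, no parallel edges. Transform
# operators append an audit record to the `transform_log` graph attribute.

#' Build a weighted graph from an edge table
#'
#' @param edges data.frame with columns `from`, `to`, `weight` (or a
#'   three-column data.frame in that order).
#' @param nodes optional character vector of node ids, to include isolated
#'   nodes; defaults to the ids appearing in `edges`.
#' @return an undirected igraph with a `weight` edge attribute.
#' @export
weighted_graph <- function(edges, nodes = NULL) {
  if (is.null(edges)) edges <- data.frame(from = character(), to = character(),
                                          weight = numeric())
  edges <- as.data.frame(edges)
  if (ncol(edges) < 3) stop("edge table needs columns from, to, weight")
  names(edges)[1:3] <- c("from", "to", "weight")
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges$weight <- as.numeric(edges$weight)
  if (any(!is.finite(edges$weight)) || any(edges$weight <= 0)) {
    stop("edge weights must be finite and > 0")
  }
  if (any(edges$from == edges$to)) stop("self-loops are not allowed")
  if (is.null(nodes)) nodes <- unique(c(edges$from, edges$to))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  if (igraph::any_multiple(g)) stop("parallel edges are not allowed")
  g
}

#' Canonical edge table of a weighted graph
#'
#' Edges as a data.frame with endpoints sorted within each row and rows
#' ordered lexicographically, so two graphs are equal iff their tables are.
#'
#' @param g weighted igraph.
#' @return data.frame with columns `from`, `to`, `weight`.
#' @export
graph_edge_table <- function(g) {
  if (igraph::ecount(g) == 0) {
    return(data.frame(from = character(), to = character(), weight = numeric(),
                      stringsAsFactors = FALSE))
  }
  el <- igraph::as_edgelist(g, names = TRUE)
  w <- igraph::E(g)$weight
  swap <- el[, 1] > el[, 2]
  tmp <- el[swap, 1]
  el[swap, 1] <- el[swap, 2]
  el[swap, 2] <- tmp
  out <- data.frame(from = el[, 1], to = el[, 2], weight = w,
                    stringsAsFactors = FALSE)
  out[order(out$from, out$to), , drop = FALSE]
}

#' Compare two weighted graphs on nodes, edges, weights and annotations
#'
#' Attribute `transform_log` is ignored.
#'
#' @param a,b weighted igraphs.
#' @param tol numeric tolerance for weights.
#' @return TRUE/FALSE.
#' @export
graphs_identical <- function(a, b, tol = 1e-9) {
  na <- sort(igraph::V(a)$name)
  nb <- sort(igraph::V(b)$name)
  if (!identical(na, nb)) return(FALSE)
  ea <- graph_edge_table(a)
  eb <- graph_edge_table(b)
  if (nrow(ea) != nrow(eb)) return(FALSE)
  rownames(ea) <- rownames(eb) <- NULL
  if (!identical(ea$from, eb$from) || !identical(ea$to, eb$to)) return(FALSE)
  if (nrow(ea) > 0 && max(abs(ea$weight - eb$weight)) > tol) return(FALSE)
  attrs_a <- setdiff(igraph::vertex_attr_names(a), "name")
  attrs_b <- setdiff(igraph::vertex_attr_names(b), "name")
  if (!identical(sort(attrs_a), sort(attrs_b))) return(FALSE)
  ord_a <- order(igraph::V(a)$name)
  ord_b <- order(igraph::V(b)$name)
  for (at in attrs_a) {
    va <- igraph::vertex_attr(a, at)[ord_a]
    vb <- igraph::vertex_attr(b, at)[ord_b]
    if (is.numeric(va) && is.numeric(vb)) {
      if (max(abs(va - vb)) > tol) return(FALSE)
    } else if (!identical(as.character(va), as.character(vb))) {
      return(FALSE)
    }
  }
  TRUE
}

# Append one audit record to the graph's transform log.
log_transform <- function(g, op, params, before, edges_added = 0L) {
  rec <- list(op = op, params = params,
              nodes_removed = igraph::vcount(before) - igraph::vcount(g),
              edges_removed = igraph::ecount(before) - igraph::ecount(g) +
                edges_added,
              edges_added = edges_added)
  log <- transform_log(before)
  igraph::graph_attr(g, "transform_log") <- c(log, list(rec))
  g
}

#' Transform log of a graph
#'
#' Ordered list of the reduction operations applied to a graph, each with its
#' parameters and node/edge deltas. [replay_transform_log()] re-applies the
#' log to the original graph and must reproduce the transformed one.
#'
#' @param g weighted igraph.
#' @return list of records (op, params, nodes_removed, edges_removed,
#'   edges_added).
#' @export
transform_log <- function(g) {
  log <- igraph::graph_attr(g, "transform_log")
  if (is.null(log)) list() else log
}

#' @rdname transform_log
#' @param original the untransformed graph.
#' @param log a transform log, as returned by [transform_log()].
#' @export
replay_transform_log <- function(original, log) {
  g <- original
  for (rec in log) {
    p <- rec$params
    g <- switch(rec$op,
      filter_edges_min_weight = filter_edges_min_weight(g, p$w),
      knn_sparsify = knn_sparsify(g, p$k, mutual = isTRUE(p$mutual)),
      filter_nodes_by_frequency = filter_nodes_by_frequency(
        g, n_genomes = p$n_genomes, min_frac = p$min_frac,
        max_frac = p$max_frac),
      filter_small_components = filter_small_components(g, p$min_size),
      keep_largest_component = keep_largest_component(g),
      contract_core_edges = contract_core_edges(g, p$w_min,
                                                combine = p$combine),
      select_nodes_by_attribute = select_nodes_by_attribute(g, p$attribute,
                                                            unlist(p$values)),
      stop("unknown operation in transform log: ", rec$op)
    )
  }
  g
}

#' Write the transform log as a TSV table
#'
#' @param g weighted igraph.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_transform_log <- function(g, path) {
  log <- transform_log(g)
  rows <- lapply(log, function(rec) {
    data.frame(op = rec$op,
               params = paste(names(rec$params),
                              vapply(rec$params, function(x)
                                paste(format(x), collapse = "|"),
                                character(1)),
                              sep = "=", collapse = ","),
               nodes_removed = rec$nodes_removed,
               edges_removed = rec$edges_removed,
               edges_added = rec$edges_added)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(op = character(), params = character(),
               nodes_removed = integer(), edges_removed = integer(),
               edges_added = integer())
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
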