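# Graph reduction operators.
#
# Each operator is pure (returns a new graph) and appends one record to the
# graph's transform_log; replay_transform_log() re-applies a log to the
# original graph and reproduces the result. All weight / frequency
# comparisons are strict, mirroring the "JSC > 0.8", "weight > 770",
# "< 1% / > 99%" conventions.

#' Remove edges at or below a weight threshold
#'
#' Keeps edges with weight strictly greater than `w`; nodes are retained
#' even when they become isolated.
#'
#' @param graph weighted igraph.
#' @param w weight threshold (strict keep on `>`).
#' @return filtered graph.
#' @export
filter_edges_min_weight <- function(graph, w) {
  out <- igraph::delete_edges(graph, igraph::E(graph)[igraph::E(graph)$weight <= w])
  log_transform(out, "filter_edges_min_weight", list(w = w), graph)
}

#' k-nearest-neighbour edge sparsification
#'
#' Each node ranks its incident edges by weight (descending, ties broken by
#' lexicographically smaller partner id). With the default union semantics an
#' edge survives iff it lies within the top-k list of at least one endpoint,
#' bounding the output at n*k edges; `mutual = TRUE` requires both endpoints.
#' The operation is idempotent at fixed k.
#'
#' @param graph weighted igraph.
#' @param k positive integer, edges retained per node.
#' @param mutual require the edge in both endpoints' top-k lists.
#' @return sparsified graph.
#' @export
knn_sparsify <- function(graph, k, mutual = FALSE) {
  stopifnot(k >= 1)
  m <- igraph::ecount(graph)
  if (m == 0) {
    return(log_transform(graph, "knn_sparsify",
                         list(k = k, mutual = mutual), graph))
  }
  el <- igraph::as_edgelist(graph, names = TRUE)
  w <- igraph::E(graph)$weight
  inc <- data.frame(node = c(el[, 1], el[, 2]),
                    partner = c(el[, 2], el[, 1]),
                    eid = rep.int(seq_len(m), 2), w = rep.int(w, 2),
                    stringsAsFactors = FALSE)
  inc <- inc[order(inc$node, -inc$w, inc$partner), ]
  by_node <- split(inc$eid, inc$node)
  kept <- lapply(by_node, function(e) e[seq_len(min(k, length(e)))])
  keep_ids <- if (mutual) {
    tab <- table(unlist(kept, use.names = FALSE))
    as.integer(names(tab)[tab == 2L])
  } else {
    unique(unlist(kept, use.names = FALSE))
  }
  out <- igraph::subgraph_from_edges(graph, igraph::E(graph)[keep_ids],
                                     delete.vertices = FALSE)
  log_transform(out, "knn_sparsify", list(k = k, mutual = mutual), graph)
}

#' Filter gene nodes (or matrix columns) by population frequency
#'
#' A gene is removed iff its genome frequency divided by `n_genomes` is
#' strictly below `min_frac` or strictly above `max_frac` (for n = 778 and
#' the 1%/99% defaults this removes frequencies < 8 and > 770, keeping both
#' bounds). Graph nodes must carry a `frequency` attribute, as set by
#' [similarity_graph()] on the genes axis and by [build_synteny_graph()].
#'
#' @param x weighted igraph with a `frequency` node attribute, or a
#'   [gpa_matrix()].
#' @param n_genomes population size the fractions refer to; defaults to the
#'   genome count for a matrix (required for a graph).
#' @param min_frac,max_frac frequency bounds as fractions of `n_genomes`.
#' @return object of the same kind as `x`.
#' @export
filter_nodes_by_frequency <- function(x, n_genomes = NULL, min_frac = 0,
                                      max_frac = 1) {
  UseMethod("filter_nodes_by_frequency")
}

#' @export
filter_nodes_by_frequency.gpa_matrix <- function(x, n_genomes = NULL,
                                                 min_frac = 0, max_frac = 1) {
  if (is.null(n_genomes)) n_genomes <- nrow(x$values)
  frac <- colSums(x$values) / n_genomes
  keep <- !(frac < min_frac | frac > max_frac)
  gpa_matrix(x$values[, keep, drop = FALSE],
             gene_annotations = x$gene_annotations,
             identity_threshold = x$identity_threshold,
             drop_empty_genes = FALSE)
}

#' @export
filter_nodes_by_frequency.igraph <- function(x, n_genomes = NULL,
                                             min_frac = 0, max_frac = 1) {
  if (is.null(n_genomes)) stop("n_genomes is required for graphs")
  if (!"frequency" %in% igraph::vertex_attr_names(x)) {
    stop("graph nodes carry no 'frequency' attribute")
  }
  freq <- igraph::V(x)$frequency
  if (anyNA(freq)) stop("missing 'frequency' on node ",
                        igraph::V(x)$name[which(is.na(freq))[1]])
  frac <- freq / n_genomes
  drop <- frac < min_frac | frac > max_frac
  out <- igraph::delete_vertices(x, igraph::V(x)[drop])
  log_transform(out, "filter_nodes_by_frequency",
                list(n_genomes = n_genomes, min_frac = min_frac,
                     max_frac = max_frac), x)
}

#' Drop small connected components
#'
#' Components with fewer than `min_size` nodes are removed entirely.
#'
#' @param graph weighted igraph.
#' @param min_size minimum component node count to keep.
#' @return filtered graph.
#' @export
filter_small_components <- function(graph, min_size) {
  comp <- igraph::components(graph)
  small <- which(comp$csize < min_size)
  out <- igraph::delete_vertices(graph,
                                 igraph::V(graph)[comp$membership %in% small])
  log_transform(out, "filter_small_components", list(min_size = min_size),
                graph)
}

#' Keep only the largest connected component
#'
#' Ties on node count are broken in favour of the component containing the
#' lexicographically smallest node id.
#'
#' @param graph non-empty weighted igraph.
#' @return the largest component as a graph.
#' @export
keep_largest_component <- function(graph) {
  if (igraph::vcount(graph) == 0) stop("graph is empty")
  comp <- igraph::components(graph)
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1) {
    firsts <- vapply(best, function(b)
      min(igraph::V(graph)$name[comp$membership == b]), character(1))
    best <- best[order(firsts)][1]
  }
  out <- igraph::delete_vertices(graph,
                                 igraph::V(graph)[comp$membership != best])
  log_transform(out, "keep_largest_component", list(), graph)
}

#' Contract highly conserved synteny edges
#'
#' Every edge whose weight (the number of genomes in which the two families
#' are adjacent) is strictly greater than `w_min` is contracted; contraction
#' is transitive, so an unbroken stretch of conserved syntenic genes
#' collapses to a single node. The merged node keeps:
#' * `member_genes`: the union of its constituents' member lists
#'   (multiplicity = list length);
#' * `multiplicity`: the member count;
#' * `frequency`: the maximum constituent frequency;
#' * its name: the lexicographically smallest member id.
#'
#' Parallel edges arising from a merge are combined keeping the maximum
#' weight by default (preserving "adjacent in W genomes" semantics);
#' `combine = "sum"` is available. The sum of multiplicities over all nodes
#' always equals the pre-contraction node count.
#'
#' @param graph synteny graph (weights are genome counts).
#' @param w_min contraction cutoff; edges with weight > `w_min` collapse.
#' @param combine how to merge parallel edge weights: `"max"` or `"sum"`.
#' @return contracted graph.
#' @export
contract_core_edges <- function(graph, w_min, combine = c("max", "sum")) {
  combine <- match.arg(combine)
  comb_fun <- if (combine == "max") max else sum
  names_v <- igraph::V(graph)$name
  members <- if ("member_genes" %in% igraph::vertex_attr_names(graph)) {
    igraph::V(graph)$member_genes
  } else {
    as.list(names_v)
  }
  freq <- if ("frequency" %in% igraph::vertex_attr_names(graph)) {
    igraph::V(graph)$frequency
  } else {
    rep(NA_real_, length(names_v))
  }
  core <- igraph::E(graph)[igraph::E(graph)$weight > w_min]
  sub <- igraph::subgraph_from_edges(graph, core, delete.vertices = FALSE)
  grp <- igraph::components(sub)$membership
  new_names <- vapply(split(names_v, grp), min, character(1))
  new_members <- lapply(split(members, grp),
                        function(x) unlist(x, use.names = FALSE))
  new_freq <- vapply(split(freq, grp), function(x)
    if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE), numeric(1))
  el <- igraph::as_edgelist(graph, names = TRUE)
  w <- igraph::E(graph)$weight
  ga <- grp[match(el[, 1], names_v)]
  gb <- grp[match(el[, 2], names_v)]
  inter <- ga != gb
  edges <- data.frame(from = new_names[as.character(pmin(ga, gb)[inter])],
                      to = new_names[as.character(pmax(ga, gb)[inter])],
                      weight = w[inter], stringsAsFactors = FALSE)
  if (nrow(edges)) {
    key <- paste(edges$from, edges$to, sep = "\r")
    aggw <- tapply(edges$weight, key, comb_fun)
    parts <- strsplit(names(aggw), "\r", fixed = TRUE)
    edges <- data.frame(from = vapply(parts, `[`, character(1), 1),
                        to = vapply(parts, `[`, character(1), 2),
                        weight = as.numeric(aggw), stringsAsFactors = FALSE)
  }
  ord <- order(as.integer(names(new_names)))
  out <- weighted_graph(edges, nodes = unname(new_names[ord]))
  out <- igraph::set_vertex_attr(
    out, "member_genes",
    value = unname(new_members[ord])[match(igraph::V(out)$name,
                                           unname(new_names[ord]))])
  # match() above is identity since nodes were supplied in this order
  out <- igraph::set_vertex_attr(
    out, "multiplicity",
    value = lengths(igraph::V(out)$member_genes))
  if (!all(is.na(new_freq))) {
    out <- igraph::set_vertex_attr(
      out, "frequency",
      value = unname(new_freq[ord])[match(igraph::V(out)$name,
                                          unname(new_names[ord]))])
  }
  igraph::graph_attr(out, "transform_log") <- NULL
  log_transform(out, "contract_core_edges",
                list(w_min = w_min, combine = combine), graph)
}

#' Induced subgraph on an attribute value set
#'
#' @param graph weighted igraph.
#' @param attribute node attribute name (must exist).
#' @param values set of attribute values to retain.
#' @return induced subgraph.
#' @export
select_nodes_by_attribute <- function(graph, attribute, values) {
  if (!attribute %in% igraph::vertex_attr_names(graph)) {
    stop("unknown node attribute: ", attribute)
  }
  v <- igraph::vertex_attr(graph, attribute)
  out <- igraph::induced_subgraph(graph, igraph::V(graph)[v %in% values])
  log_transform(out, "select_nodes_by_attribute",
                list(attribute = attribute, values = values), graph)
}
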