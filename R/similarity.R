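# Pairwise similarity over the binary presence/absence matrix.
#
# The genome-genome graph uses rows (isolates), the gene-gene co-occurrence
# graph uses columns (gene families) of the same matrix. All metrics return
# similarities ("larger = more alike"): Jaccard and cosine are native
# similarities on presence sets; Euclidean distance d is mapped through
# 1/(1+d) so that all graphs share the same weight contract.

#' Pairwise similarity between genomes or genes
#'
#' For binary presence vectors u, v:
#' * `jaccard`: |u n v| / |u u v| (shared over total);
#' * `cosine`: |u n v| / sqrt(|u| * |v|);
#' * `euclidean_sim`: 1 / (1 + d(u, v)) with d the Euclidean distance.
#'
#' A pair with an empty union (both vectors all-zero, possible after the
#' accessory filter) is given similarity 0, not NaN.
#'
#' @param matrix a [gpa_matrix()].
#' @param axis `"genomes"` (rows) or `"genes"` (columns).
#' @param metric `"jaccard"`, `"cosine"` or `"euclidean_sim"`.
#' @param accessory_only drop core gene families before computing
#'   (axis = "genomes" only): families present in at least
#'   `core_fraction` of genomes are excluded.
#' @param core_fraction fraction defining "core" for `accessory_only`;
#'   the default 1 excludes only families present in 100% of genomes.
#' @return a `similarity_matrix`: list with `ids`, symmetric `values`
#'   matrix, `metric`, and (axis = "genes") the per-gene genome `frequency`.
#' @export
pairwise_similarity <- function(matrix,
                                axis = c("genomes", "genes"),
                                metric = c("jaccard", "cosine",
                                           "euclidean_sim"),
                                accessory_only = FALSE,
                                core_fraction = 1) {
  stopifnot(is_gpa_matrix(matrix))
  axis <- match.arg(axis)
  metric <- match.arg(metric)
  x <- matrix$values
  if (accessory_only) {
    if (axis != "genomes") {
      stop("accessory_only applies to axis = \"genomes\" only")
    }
    keep <- colSums(x) < core_fraction * nrow(x)
    x <- x[, keep, drop = FALSE]
  }
  if (axis == "genes") x <- t(x)
  if (nrow(x) < 2) {
    stop("need at least 2 items on axis \"", axis, "\" (have ", nrow(x), ")")
  }
  frequency <- if (axis == "genes") rowSums(x) else NULL
  inter <- tcrossprod(x)  # |u n v|
  sizes <- diag(inter)
  s <- switch(metric,
    jaccard = {
      un <- outer(sizes, sizes, `+`) - inter
      out <- inter / un
      out[un == 0] <- 0
      out
    },
    cosine = {
      denom <- sqrt(outer(sizes, sizes))
      out <- inter / denom
      out[denom == 0] <- 0
      out
    },
    euclidean_sim = {
      d2 <- outer(sizes, sizes, `+`) - 2 * inter
      1 / (1 + sqrt(pmax(d2, 0)))
    })
  dimnames(s) <- list(rownames(x), rownames(x))
  structure(list(ids = rownames(x), values = s, metric = metric,
                 frequency = frequency, axis = axis),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("similarity_matrix: %d %s, metric = %s\n", length(x$ids),
              x$axis, x$metric))
  invisible(x)
}

#' Materialise a similarity matrix as a weighted graph
#'
#' One node per item; an edge (u, v) is created iff similarity(u, v) is
#' strictly greater than `min_weight` (matching the strict "JSC > t"
#' convention used throughout). With `min_weight = 0`, every pair sharing
#' anything is connected, so a population in which all pairs share at least
#' one family yields the complete graph with n(n-1)/2 edges.
#'
#' @param sim a `similarity_matrix` from [pairwise_similarity()].
#' @param min_weight similarity threshold (strict), >= 0.
#' @return weighted igraph; gene graphs carry a `frequency` node attribute.
#' @export
similarity_graph <- function(sim, min_weight = 0) {
  stopifnot(inherits(sim, "similarity_matrix"), min_weight >= 0)
  s <- sim$values
  n <- nrow(s)
  idx <- which(upper.tri(s) & s > min_weight, arr.ind = TRUE)
  edges <- data.frame(from = sim$ids[idx[, 1]], to = sim$ids[idx[, 2]],
                      weight = s[idx], stringsAsFactors = FALSE)
  g <- weighted_graph(edges, nodes = sim$ids)
  if (!is.null(sim$frequency)) {
    g <- igraph::set_vertex_attr(
      g, "frequency",
      value = as.numeric(sim$frequency[match(igraph::V(g)$name, sim$ids)]))
  }
  igraph::graph_attr(g, "metric") <- sim$metric
  g
}
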