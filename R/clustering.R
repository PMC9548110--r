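# Graph clustering: Markov clustering (MCL) for the similarity networks,
# Louvain modularity optimisation for the synteny networks.

#' Cluster assignment container
#'
#' @param labels named integer vector: node id -> cluster label (1..K).
#' @param method `"mcl"` or `"louvain"`.
#' @param parameter inflation (MCL) or granularity/resolution (Louvain).
#' @return object of class `cluster_assignment`.
#' @export
cluster_assignment <- function(labels, method = c("mcl", "louvain"),
                               parameter = NA_real_) {
  method <- match.arg(method)
  stopifnot(!is.null(names(labels)), !anyNA(labels))
  labels <- stats::setNames(as.integer(labels), names(labels))
  structure(labels, method = method, parameter = parameter,
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: %d nodes in %d clusters (%s, parameter %s)\n",
              length(x), length(unique(unclass(x))), attr(x, "method"),
              format(attr(x, "parameter"))))
  invisible(x)
}

#' Sizes of the clusters in an assignment
#'
#' @param assignment a `cluster_assignment`.
#' @return integer vector of sizes, named by cluster label.
#' @export
cluster_sizes <- function(assignment) {
  tab <- table(unclass(assignment))
  stats::setNames(as.integer(tab), names(tab))
}

#' Markov clustering (MCL) of a weighted graph
#'
#' Deterministic MCL on the weighted adjacency matrix. Numeric policy:
#' self-loops are added with weight equal to the node's maximum incident
#' weight (1 for isolated nodes); columns are normalised to stochastic;
#' iterations alternate expansion (matrix square) and inflation
#' (element-wise power `inflation`, renormalise) with entries below 1e-6
#' pruned, until the maximum entry change drops below 1e-8 or 200
#' iterations. Clusters are read off the attractor structure of the limit
#' matrix. The algorithm runs independently per connected component, so
#' clusters never span components. Labels are size-ranked via
#' [rank_clusters()].
#'
#' @param graph non-empty weighted igraph.
#' @param inflation MCL inflation parameter (MCLi), must be > 1.
#' @param prune entry pruning threshold.
#' @param tol convergence tolerance on the maximum entry change.
#' @param max_iter iteration cap.
#' @return a `cluster_assignment`.
#' @export
mcl_cluster <- function(graph, inflation = 2, prune = 1e-6, tol = 1e-8,
                        max_iter = 200) {
  if (igraph::vcount(graph) == 0) stop("graph is empty")
  if (inflation <= 1) stop("inflation must be > 1")
  comp <- igraph::components(graph)
  labels <- integer(igraph::vcount(graph))
  names(labels) <- igraph::V(graph)$name
  next_label <- 1L
  for (ci in seq_len(comp$no)) {
    vids <- which(comp$membership == ci)
    sub <- igraph::induced_subgraph(graph, vids)
    part <- mcl_component(sub, inflation, prune, tol, max_iter)
    labels[igraph::V(sub)$name] <- part + next_label - 1L
    next_label <- next_label + max(part)
  }
  rank_clusters(cluster_assignment(labels, "mcl", inflation))
}

# MCL on one connected component (dense).
mcl_component <- function(sub, inflation, prune, tol, max_iter) {
  n <- igraph::vcount(sub)
  if (n == 1) return(stats::setNames(1L, igraph::V(sub)$name))
  a <- igraph::as_adjacency_matrix(sub, attr = "weight", sparse = FALSE)
  loop <- apply(a, 1, max)
  loop[loop == 0] <- 1
  diag(a) <- loop
  m <- sweep(a, 2, colSums(a), "/")
  for (i in seq_len(max_iter)) {
    m2 <- m %*% m                      # expansion
    m2 <- m2^inflation                 # inflation
    m2[m2 < prune] <- 0
    cs <- colSums(m2)
    cs[cs == 0] <- 1
    m2 <- sweep(m2, 2, cs, "/")
    delta <- max(abs(m2 - m))
    m <- m2
    if (delta < tol) break
  }
  interpret_mcl_matrix(m, igraph::V(sub)$name)
}

# Read clusters from a converged MCL matrix: attractors are nodes with mass
# on their own diagonal; each attractor row spans the nodes it attracts;
# overlapping attractor sets are merged (union-find).
interpret_mcl_matrix <- function(m, node_names) {
  n <- nrow(m)
  eps <- 1e-9
  attractors <- which(diag(m) > eps)
  if (!length(attractors)) attractors <- which.max(diag(m))
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  for (a in attractors) {
    for (j in which(m[a, ] > eps)) union(a, j)
  }
  # safety net: nodes attracted by nothing join their heaviest column entry
  for (j in seq_len(n)) {
    if (all(m[, j] <= eps)) next
    union(j, which.max(m[, j]))
  }
  roots <- vapply(seq_len(n), find, integer(1))
  part <- as.integer(factor(roots))
  stats::setNames(part, node_names)
}

#' Louvain clustering of a weighted graph
#'
#' Weighted Louvain modularity optimisation with a resolution-like
#' granularity parameter; smaller values give coarser clusterings. The node
#' sweep order is shuffled deterministically from `seed`, so a fixed
#' (graph, granularity, seed) triple always returns the same assignment.
#'
#' @param graph non-empty weighted igraph.
#' @param granularity resolution parameter, > 0.
#' @param seed integer seed for the node sweep order.
#' @return a `cluster_assignment`.
#' @export
louvain_cluster <- function(graph, granularity = 1, seed = 1L) {
  if (igraph::vcount(graph) == 0) stop("graph is empty")
  if (granularity <= 0) stop("granularity must be > 0")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  # seed both the sweep-order shuffle and igraph's RNG (which draws from R's)
  set.seed(seed)
  ord <- sample.int(igraph::vcount(graph))
  shuffled <- igraph::permute(graph, order(ord))
  cl <- igraph::cluster_louvain(shuffled, weights = igraph::E(shuffled)$weight,
                                resolution = granularity)
  labels <- stats::setNames(igraph::membership(cl)[igraph::V(graph)$name],
                            igraph::V(graph)$name)
  rank_clusters(cluster_assignment(labels, "louvain", granularity))
}

#' Rank cluster labels by size
#'
#' Relabels clusters 1..K by decreasing size; ties are broken in favour of
#' the cluster containing the lexicographically smallest node id. Membership
#' is unchanged.
#'
#' @param assignment a `cluster_assignment` (or named integer vector).
#' @return a `cluster_assignment` with size-ranked labels.
#' @export
rank_clusters <- function(assignment) {
  labels <- unclass(assignment)
  method <- attr(assignment, "method")
  parameter <- attr(assignment, "parameter")
  if (is.null(method)) method <- "mcl"
  groups <- split(names(labels), labels)
  sizes <- lengths(groups)
  firsts <- vapply(groups, min, character(1))
  ord <- order(-sizes, firsts)
  relabel <- stats::setNames(seq_along(ord), names(groups)[ord])
  out <- stats::setNames(relabel[as.character(labels)], names(labels))
  cluster_assignment(out, method, parameter)
}

#' Write a cluster assignment as a node-to-cluster TSV
#'
#' @param assignment a `cluster_assignment`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_clusters <- function(assignment, path) {
  tab <- data.frame(node = names(assignment),
                    cluster = as.integer(assignment))
  tab <- tab[order(tab$cluster, tab$node), ]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
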