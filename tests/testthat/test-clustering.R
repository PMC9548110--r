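# clustering: MCL vs the independent reference implementation, Louvain vs
# brute-force modularity, size-ranked labels.

two_cliques <- function(k = 4, w_bridge = 1) {
  nodes_a <- sprintf("a%d", seq_len(k))
  nodes_b <- sprintf("b%d", seq_len(k))
  edges <- rbind(
    do.call(rbind, lapply(combn(nodes_a, 2, simplify = FALSE), function(p)
      data.frame(from = p[1], to = p[2], weight = 1))),
    do.call(rbind, lapply(combn(nodes_b, 2, simplify = FALSE), function(p)
      data.frame(from = p[1], to = p[2], weight = 1))),
    data.frame(from = "a1", to = "b1", weight = w_bridge))
  weighted_graph(edges)
}

test_that("MCL: components are never merged; isolated nodes are singletons", {
  g <- make_wgraph("a", "b", 1, "b", "c", 1, "a", "c", 1,
                   "x", "y", 1, "y", "z", 1, "x", "z", 1)
  for (infl in c(1.2, 2, 5)) {
    cl <- mcl_cluster(g, infl)
    expect_equal(length(unique(unclass(cl))), 2L)
    expect_true(same_partition(
      setNames(as.character(cl), names(cl)),
      c(a = "1", b = "1", c = "1", x = "2", y = "2", z = "2")))
  }
  iso <- weighted_graph(data.frame(from = "a", to = "b", weight = 1),
                        nodes = c("a", "b", "solo"))
  cl <- mcl_cluster(iso, 2)
  expect_equal(sum(unclass(cl) == cl[["solo"]]), 1L)
})

test_that("MCL splits two cliques at the bridge (reference oracle)", {
  g <- two_cliques(4)
  cl <- mcl_cluster(g, 2)
  expect_equal(length(unique(unclass(cl))), 2L)
  want <- oracle_mcl(g, 2)
  expect_true(same_partition(setNames(as.character(cl), names(cl)),
                             setNames(as.character(want), names(want))))
})

test_that("MCL is deterministic and validates inflation", {
  g <- random_weighted_graph(10, 0.4, seed = 1)
  expect_identical(mcl_cluster(g, 2), mcl_cluster(g, 2))
  expect_error(mcl_cluster(g, 1), "inflation")
  expect_error(mcl_cluster(weighted_graph(NULL, nodes = character(0)), 2),
               "empty")
})

test_that("MCL matches the reference implementation on random graphs", {
  mismatches <- 0L
  for (s in 1:50) {
    n <- sample(4:12, 1)
    g <- random_weighted_graph(n, p = 0.45, seed = 1000 + s)
    infl <- sample(c(1.5, 2, 3), 1)
    got <- mcl_cluster(g, infl)
    want <- oracle_mcl(g, infl)
    ok <- same_partition(setNames(as.character(got), names(got)),
                         setNames(as.character(want), names(want)))
    if (!ok) mismatches <- mismatches + 1L
    expect_true(ok, info = sprintf("seed %d inflation %.1f", s, infl))
  }
  expect_identical(mismatches, 0L)
})

test_that("Louvain: components, cliques, and brute-force modularity", {
  g <- make_wgraph("a", "b", 1, "b", "c", 1, "a", "c", 1,
                   "x", "y", 1, "y", "z", 1, "x", "z", 1)
  cl <- louvain_cluster(g, 1, seed = 7)
  expect_equal(length(unique(unclass(cl))), 2L)

  k5 <- weighted_graph(do.call(rbind, lapply(
    combn(sprintf("n%d", 1:5), 2, simplify = FALSE),
    function(p) data.frame(from = p[1], to = p[2], weight = 1))))
  cl5 <- louvain_cluster(k5, 1, seed = 1)
  best5 <- max_modularity_partition(k5, 1)
  expect_equal(length(unique(unclass(cl5))), length(unique(best5$membership)))

  cc <- two_cliques(4)
  clc <- louvain_cluster(cc, 1, seed = 3)
  best <- max_modularity_partition(cc, 1)
  expect_true(same_partition(setNames(as.character(clc), names(clc)),
                             setNames(as.character(best$membership),
                                      names(best$membership))))
  expect_equal(oracle_modularity(cc, setNames(unclass(clc), names(clc)), 1),
               best$q, tolerance = 1e-9)
})

test_that("Louvain reaches the exhaustive optimum on small planted graphs", {
  for (s in 1:6) {
    set.seed(s)
    nodes <- sprintf("v%d", 1:8)
    groups <- rep(1:2, each = 4)
    pairs <- t(combn(1:8, 2))
    p <- ifelse(groups[pairs[, 1]] == groups[pairs[, 2]], 0.95, 0.15)
    keep <- runif(nrow(pairs)) < p
    if (sum(keep) < 4) next
    g <- weighted_graph(data.frame(from = nodes[pairs[keep, 1]],
                                   to = nodes[pairs[keep, 2]],
                                   weight = runif(sum(keep), 0.5, 1)),
                        nodes = nodes)
    cl <- louvain_cluster(g, 1, seed = 42)
    best <- max_modularity_partition(g, 1)
    got_q <- oracle_modularity(g, setNames(unclass(cl), names(cl)), 1)
    expect_equal(got_q, best$q, tolerance = 1e-9,
                 info = sprintf("seed %d", s))
  }
})

test_that("Louvain is seed-deterministic, beats singletons, checks input", {
  g <- random_weighted_graph(12, 0.4, seed = 5)
  expect_identical(louvain_cluster(g, 1, seed = 9),
                   louvain_cluster(g, 1, seed = 9))
  cl <- louvain_cluster(g, 1, seed = 9)
  q <- oracle_modularity(g, setNames(unclass(cl), names(cl)), 1)
  q_single <- oracle_modularity(
    g, setNames(seq_len(igraph::vcount(g)), igraph::V(g)$name), 1)
  expect_gte(q, q_single)
  expect_error(louvain_cluster(g, 0), "granularity")
})

test_that("smaller granularity is coarser on a modular graph", {
  g <- two_cliques(5)
  k_coarse <- length(unique(unclass(louvain_cluster(g, 0.2, seed = 1))))
  k_fine <- length(unique(unclass(louvain_cluster(g, 2, seed = 1))))
  expect_lte(k_coarse, k_fine)
})

test_that("rank_clusters orders labels by size with id tie-break", {
  asn <- cluster_assignment(
    c(setNames(rep(10L, 3), c("p", "q", "r")),
      setNames(rep(20L, 7), sprintf("m%d", 1:7))), "mcl")
  ranked <- rank_clusters(asn)
  expect_equal(unname(unclass(ranked)[["m1"]]), 1L)  # size 7 -> label 1
  expect_equal(unname(unclass(ranked)[["p"]]), 2L)
  # equal sizes: the cluster containing the smallest id wins
  tie <- cluster_assignment(c(x = 5L, z = 5L, a = 9L, b = 9L), "mcl")
  ranked2 <- rank_clusters(tie)
  expect_equal(unname(unclass(ranked2)[["a"]]), 1L)
  expect_equal(unname(unclass(ranked2)[["x"]]), 2L)
  one <- rank_clusters(cluster_assignment(c(a = 4L), "mcl"))
  expect_equal(unname(unclass(one)[["a"]]), 1L)
  # membership unchanged
  expect_true(same_partition(
    setNames(as.character(ranked), names(ranked)),
    setNames(as.character(asn), names(asn))))
})

test_that("assignments are partitions with labels 1..K, label 1 largest", {
  for (s in 1:5) {
    g <- random_weighted_graph(15, 0.3, seed = s + 300)
    cl <- mcl_cluster(g, 2)
    expect_setequal(names(cl), igraph::V(g)$name)
    k <- length(unique(unclass(cl)))
    expect_setequal(unique(unclass(cl)), seq_len(k))
    sizes <- cluster_sizes(cl)
    expect_equal(unname(sizes[as.character(1)]), max(sizes))
  }
})
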