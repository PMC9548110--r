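# graph_transforms: reduction operators, k-NN oracle, contraction laws,
# transform-log replay.

test_that("edge weight filter keeps strictly greater weights", {
  g <- make_wgraph("a", "b", 0.9, "b", "c", 0.8, "c", "d", 0.7)
  out <- filter_edges_min_weight(g, 0.8)
  expect_equal(igraph::ecount(out), 1L)
  expect_equal(igraph::E(out)$weight, 0.9)
  expect_equal(igraph::vcount(out), 4L)  # nodes retained when isolated
  expect_equal(igraph::ecount(filter_edges_min_weight(g, 0)), 3L)
  expect_equal(igraph::ecount(filter_edges_min_weight(g, Inf)), 0L)
})

test_that("k-NN union semantics on the worked examples", {
  tri <- make_wgraph("a", "b", 3, "b", "c", 2, "a", "c", 1)
  out <- graph_edge_table(knn_sparsify(tri, 1))
  expect_identical(paste(out$from, out$to), c("a b", "b c"))
  star <- make_wgraph("hub", "l1", 1, "hub", "l2", 2, "hub", "l3", 3,
                      "hub", "l4", 4, "hub", "l5", 5)
  expect_equal(igraph::ecount(knn_sparsify(star, 3)), 5L)
  # k >= max degree leaves the graph unchanged
  expect_true(graphs_identical(knn_sparsify(tri, 2), tri))
})

test_that("k-NN matches the exhaustive oracle on random graphs", {
  for (s in 1:12) {
    n <- sample(4:15, 1)
    g <- random_weighted_graph(n, p = 0.5, seed = s)
    for (k in c(1, 2, 4)) {
      for (mutual in c(FALSE, TRUE)) {
        got <- graph_edge_table(knn_sparsify(g, k, mutual = mutual))
        want <- oracle_knn_edges(g, k, mutual = mutual)
        expect_identical(paste(got$from, got$to),
                         paste(want$from, want$to),
                         info = sprintf("seed %d k %d mutual %s", s, k, mutual))
      }
    }
  }
})

test_that("k-NN is idempotent and bounded by n*k", {
  for (s in 1:5) {
    g <- random_weighted_graph(12, p = 0.6, seed = s + 50)
    for (k in c(1, 3)) {
      once <- knn_sparsify(g, k)
      expect_lte(igraph::ecount(once), igraph::vcount(g) * k)
      expect_true(graphs_identical(knn_sparsify(once, k), once))
    }
  }
})

test_that("k-NN tie-break is deterministic (weight, then partner id)", {
  g <- make_wgraph("x", "b", 1, "x", "a", 1, "x", "c", 2)
  out <- graph_edge_table(knn_sparsify(g, 2))
  # top-2 of x: c (weight 2) then a (tie at 1, smaller id); but x-b survives
  # via b's own top-k, so check via mutual semantics
  out_m <- graph_edge_table(knn_sparsify(g, 2, mutual = TRUE))
  expect_identical(paste(out_m$from, out_m$to), c("a x", "c x"))
  expect_identical(nrow(out), 3L)
})

test_that("frequency filter: strict bounds reproduce the 778-genome rules", {
  freqs <- c(f_core = 778, f_hi = 771, f_edge = 770, f8 = 8, f7 = 7)
  edges <- data.frame(from = names(freqs)[1:4], to = names(freqs)[2:5],
                      weight = 1)
  g <- weighted_graph(edges)
  g <- igraph::set_vertex_attr(g, "frequency",
                               value = unname(freqs[igraph::V(g)$name]))
  out <- filter_nodes_by_frequency(g, n_genomes = 778, min_frac = 0.01,
                                   max_frac = 0.99)
  kept <- igraph::V(out)$name
  expect_false("f_core" %in% kept)   # 778/778 > 0.99
  expect_false("f_hi" %in% kept)     # 771/778 > 0.99
  expect_true("f_edge" %in% kept)    # 770/778 not > 0.99
  expect_true("f8" %in% kept)        # 8/778 ~ 1.03% not < 1%
  expect_false("f7" %in% kept)       # 7/778 ~ 0.90% < 1%
})

test_that("frequency filter on matrices and error on missing attribute", {
  m <- random_binary_gpa(10, 20, seed = 2)
  out <- filter_nodes_by_frequency(m, min_frac = 0.25, max_frac = 0.75)
  fr <- gene_frequencies(m) / 10
  expect_setequal(gene_ids(out), names(fr)[fr >= 0.25 & fr <= 0.75])
  g <- make_wgraph("a", "b", 1)
  expect_error(filter_nodes_by_frequency(g, n_genomes = 10), "frequency")
})

test_that("small-component filter and largest-component selection", {
  g <- make_wgraph("a", "b", 1, "b", "c", 1, "x", "y", 1)
  g <- igraph::add_vertices(g, 1, name = "solo")
  out <- filter_small_components(g, 3)
  expect_setequal(igraph::V(out)$name, c("a", "b", "c"))
  expect_true(graphs_identical(filter_small_components(g, 1), g))
  out2 <- filter_small_components(g, 2)
  expect_false("solo" %in% igraph::V(out2)$name)

  expect_setequal(igraph::V(keep_largest_component(g))$name, c("a", "b", "c"))
  # tie on size -> component holding the smallest node id
  tie <- make_wgraph("c", "d", 1, "a", "b", 1)
  expect_setequal(igraph::V(keep_largest_component(tie))$name, c("a", "b"))
  conn <- make_wgraph("a", "b", 1)
  expect_true(graphs_identical(keep_largest_component(conn), conn))
  expect_error(keep_largest_component(weighted_graph(NULL,
                                                     nodes = character(0))),
               "empty")
})

test_that("contraction collapses conserved chains transitively", {
  path <- make_wgraph("a", "b", 10, "b", "c", 10)
  out <- contract_core_edges(path, 9)
  expect_equal(igraph::vcount(out), 1L)
  expect_equal(igraph::ecount(out), 0L)
  expect_identical(igraph::V(out)$multiplicity, 3L)
  expect_setequal(igraph::V(out)$member_genes[[1]], c("a", "b", "c"))

  mixed <- make_wgraph("a", "b", 10, "b", "c", 5)
  out2 <- contract_core_edges(mixed, 9)
  expect_identical(sort(igraph::V(out2)$name), c("a", "c"))
  expect_equal(graph_edge_table(out2)$weight, 5)
  expect_identical(igraph::V(out2)$multiplicity[
    match("a", igraph::V(out2)$name)], 2L)
})

test_that("contraction merges parallel edges by max (sum by flag)", {
  # square a-b (core), a-c 3, b-c 7: after contracting ab, two c edges merge
  g <- make_wgraph("a", "b", 100, "a", "c", 3, "b", "c", 7)
  out <- contract_core_edges(g, 99)
  expect_equal(graph_edge_table(out)$weight, 7)
  out_sum <- contract_core_edges(g, 99, combine = "sum")
  expect_equal(graph_edge_table(out_sum)$weight, 10)
})

test_that("contraction conserves total multiplicity and frequency max", {
  for (s in 1:5) {
    g <- random_weighted_graph(12, p = 0.4, seed = s,
                               weights = function(m) sample(1:20, m, TRUE))
    g <- igraph::set_vertex_attr(g, "frequency",
                                 value = sample(1:20, 12, TRUE))
    g <- igraph::set_vertex_attr(g, "member_genes",
                                 value = as.list(igraph::V(g)$name))
    out <- contract_core_edges(g, 10)
    expect_identical(sum(igraph::V(out)$multiplicity), 12L)
    expect_lte(igraph::ecount(out), igraph::ecount(g))
    # merged frequency = max over members
    freq_in <- setNames(igraph::V(g)$frequency, igraph::V(g)$name)
    for (i in seq_len(igraph::vcount(out))) {
      expect_equal(igraph::V(out)$frequency[i],
                   max(freq_in[igraph::V(out)$member_genes[[i]]]))
    }
  }
})

test_that("attribute selection induces the right subgraph", {
  g <- make_wgraph("a", "b", 1, "b", "c", 1, "c", "d", 1)
  g <- igraph::set_vertex_attr(g, "CC", value = c("CC5", "CC5", "CC8", "CC8"))
  out <- select_nodes_by_attribute(g, "CC", "CC5")
  expect_setequal(igraph::V(out)$name, c("a", "b"))
  expect_equal(igraph::ecount(out), 1L)
  expect_true(graphs_identical(
    select_nodes_by_attribute(g, "CC", c("CC5", "CC8")), g))
  expect_equal(igraph::vcount(
    select_nodes_by_attribute(g, "CC", character(0))), 0L)
  expect_error(select_nodes_by_attribute(g, "ST", "x"), "unknown")
})

test_that("transform log replays to the transformed graph", {
  g <- random_weighted_graph(14, p = 0.5, seed = 9,
                             weights = function(m) sample(1:30, m, TRUE))
  g <- igraph::set_vertex_attr(g, "frequency",
                               value = sample(1:30, 14, TRUE))
  out <- filter_edges_min_weight(g, 5)
  out <- knn_sparsify(out, 3)
  out <- keep_largest_component(out)
  out <- contract_core_edges(out, 25)
  log <- transform_log(out)
  expect_identical(vapply(log, `[[`, character(1), "op"),
                   c("filter_edges_min_weight", "knn_sparsify",
                     "keep_largest_component", "contract_core_edges"))
  expect_true(all(vapply(log, function(r)
    r$nodes_removed >= 0 && r$edges_removed >= 0, logical(1))))
  replayed <- replay_transform_log(g, log)
  expect_true(graphs_identical(out, replayed))
  f <- tempfile()
  write_transform_log(out, f)
  expect_identical(nrow(read.delim(f)), 4L)
})
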