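# synthetic_pangenome: determinism, planted structure, recovery metrics.

test_that("pure-core config gives an all-ones matrix and a core cycle", {
  ds <- simulate_pangenome(synthetic_pangenome_config(
    n_lineages = 2, genomes_per_lineage = 10, n_core = 100,
    blocks_per_lineage = 0, n_mge = 0, n_singletons = 0, seed = 3))
  expect_equal(dim(ds$matrix$values), c(20L, 100L))
  expect_true(all(ds$matrix$values == 1L))
  g <- build_synteny_graph(ds$orders)
  expect_equal(igraph::ecount(g), 100L)
  expect_true(all(igraph::E(g)$weight == 20))
  # whole backbone contracts to one node
  ct <- contract_core_edges(g, floor(0.99 * 20))
  expect_equal(igraph::vcount(ct), 1L)
  expect_identical(igraph::V(ct)$multiplicity, 100L)
})

test_that("same seed gives bit-identical datasets; seeds differ", {
  a <- simulate_pangenome(seed = 7)
  b <- simulate_pangenome(seed = 7)
  expect_identical(a$matrix$values, b$matrix$values)
  expect_identical(a$orders, b$orders)
  expect_identical(a$truth, b$truth)
  c <- simulate_pangenome(seed = 8)
  expect_false(identical(a$matrix$values, c$matrix$values))
})

test_that("gene and genome counts follow the config arithmetic", {
  cfg <- synthetic_pangenome_config(n_lineages = 3, genomes_per_lineage = 20,
                                    n_core = 200, blocks_per_lineage = 3,
                                    block_size = 10, n_mge = 4, mge_size = 8,
                                    n_singletons = 30, seed = 1)
  ds <- simulate_pangenome(cfg)
  expect_equal(nrow(ds$matrix$values), 60L)
  expect_equal(ncol(ds$matrix$values), 200 + 3 * 3 * 10 + 4 * 8 + 30)
  # core frequency identically 1
  core <- names(ds$truth$gene_block)[ds$truth$gene_block == "core"]
  expect_true(all(gene_frequencies(ds$matrix)[core] == 60))
  # singletons occur in exactly one genome
  sing <- names(ds$truth$gene_block)[ds$truth$gene_block == "singleton"]
  expect_true(all(gene_frequencies(ds$matrix)[sing] == 1))
})

test_that("degenerate probabilities pin block carriage exactly", {
  ds <- simulate_pangenome(synthetic_pangenome_config(
    n_lineages = 2, genomes_per_lineage = 5, n_core = 50,
    blocks_per_lineage = 1, block_size = 4, p_in = 1, p_leak = 0,
    n_mge = 0, n_singletons = 0, seed = 2))
  blocks <- unique(ds$truth$gene_block)
  blocks <- blocks[blocks != "core"]
  for (b in blocks) {
    genes <- names(ds$truth$gene_block)[ds$truth$gene_block == b]
    lin <- sub("\\.B\\d+$", "", b)
    carriers <- rownames(ds$matrix$values)[ds$matrix$values[, genes[1]] == 1]
    expect_setequal(carriers,
                    names(ds$truth$genome_lineage)[
                      ds$truth$genome_lineage == lin])
  }
  expect_error(synthetic_pangenome_config(p_in = 1.2), "probabilities")
  expect_error(synthetic_pangenome_config(genomes_per_lineage = 1),
               "at least 2")
})

test_that("carried blocks sit contiguously at their backbone locus", {
  ds <- simulate_pangenome(seed = 5)
  carriage <- ds$truth$block_carriage
  for (g in sample(rownames(carriage), 5)) {
    ord <- as.character(ds$orders[[g]][[1]])
    for (b in colnames(carriage)) {
      genes <- names(ds$truth$gene_block)[ds$truth$gene_block == b]
      if (carriage[g, b]) {
        pos <- match(genes, ord)
        expect_false(anyNA(pos))
        expect_equal(pos, seq(min(pos), length.out = length(genes)))
      } else {
        expect_true(all(is.na(match(genes, ord))))
      }
    }
  }
})

test_that("MGE carriage is independent of lineage (aggregate chi-square)", {
  # pool carrier counts over 30 seeds; independence must not be rejected
  tab <- matrix(0, 3, 2)
  for (s in 1:30) {
    ds <- simulate_pangenome(synthetic_pangenome_config(seed = 6000 + s))
    lin <- ds$truth$genome_lineage
    carriage <- ds$truth$block_carriage[, grepl("^MGE",
                                                colnames(ds$truth$block_carriage)),
                                        drop = FALSE]
    for (l in seq_along(unique(lin))) {
      rows <- names(lin)[lin == unique(lin)[l]]
      tab[l, 1] <- tab[l, 1] + sum(carriage[rows, ])
      tab[l, 2] <- tab[l, 2] + sum(!carriage[rows, ])
    }
  }
  p <- suppressWarnings(stats::chisq.test(tab)$p.value)
  expect_gt(p, 0.01)
})

test_that("ARI and pairwise F1 behave on the canonical cases", {
  truth <- c(a = "x", b = "x", c = "y", d = "y")
  expect_equal(adjusted_rand_index(truth, truth), 1)
  # one blob vs >= 2 planted groups -> 0
  blob <- setNames(rep("z", 4), names(truth))
  expect_equal(adjusted_rand_index(blob, truth), 0)
  # label permutation invariance
  perm <- c(a = "9", b = "9", c = "1", d = "1")
  expect_equal(adjusted_rand_index(perm, truth), 1)
  expect_equal(pairwise_f1(truth, truth), 1)
  expect_equal(pairwise_f1(perm, truth), 1)
  split_all <- setNames(letters[1:4], names(truth))
  expect_equal(pairwise_f1(split_all, truth), 0)
})

test_that("truth_metrics scores assignments against the planted truth", {
  ds <- simulate_pangenome(synthetic_pangenome_config(
    n_lineages = 2, genomes_per_lineage = 5, n_core = 30,
    blocks_per_lineage = 1, block_size = 5, n_mge = 1, mge_size = 4,
    n_singletons = 5, seed = 4))
  perfect_genomes <- cluster_assignment(setNames(
    as.integer(factor(ds$truth$genome_lineage)),
    names(ds$truth$genome_lineage)))
  blocks <- ds$truth$gene_block
  gene_names <- names(blocks)[!blocks %in% c("core", "singleton")]
  perfect_genes <- cluster_assignment(setNames(
    as.integer(factor(blocks[gene_names])), gene_names))
  tm <- truth_metrics(ds, perfect_genomes, perfect_genes)
  expect_equal(tm$lineage_ari, 1)
  expect_equal(tm$block_f1, 1)
})

test_that("synthetic dataset writes to plain-text files and reloads", {
  ds <- simulate_pangenome(synthetic_pangenome_config(
    n_lineages = 2, genomes_per_lineage = 3, n_core = 20,
    blocks_per_lineage = 1, block_size = 3, n_mge = 1, mge_size = 2,
    n_singletons = 2, seed = 9))
  dir <- file.path(tempdir(), "synth_out")
  write_synthetic_pangenome(ds, dir)
  m <- suppressMessages(
    read_presence_absence(file.path(dir, "matrix.rtab"), "rtab"))
  # reloading enforces the no-all-zero-column invariant, so compare on the
  # families that drew at least one carrier
  nonzero <- gene_ids(ds$matrix)[gene_frequencies(ds$matrix) > 0]
  expect_identical(m$values[genome_ids(ds$matrix), nonzero],
                   ds$matrix$values[, nonzero])
  md <- read_metadata(file.path(dir, "metadata.tsv"))
  expect_setequal(md$genome_id, genome_ids(ds$matrix))
  expect_true(file.exists(file.path(dir, "orders.tsv")))
  expect_true(file.exists(file.path(dir, "truth.tsv")))
})
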