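# Seed-deterministic synthetic pangenome generator.
#
# The stated world: a few clonal lineages, each carrying lineage-restricted
# accessory gene blocks at high within-lineage probability with a small
# leak rate outside; mobile-element blocks carried sporadically and
# independently of lineage; core genes in every genome; singleton noise
# genes in exactly one genome each; and per-genome circular gene orders in
# which carried blocks are spliced into a fixed core backbone at fixed loci.
# All sampling is drawn from a single RNG stream in a fixed documented
# order, so a seed pins the dataset bit-for-bit.

#' Configuration for the synthetic pangenome generator
#'
#' @param n_lineages number of clonal lineages (>= 1).
#' @param genomes_per_lineage genomes per lineage (>= 2).
#' @param n_core core gene count (frequency 1 by construction).
#' @param blocks_per_lineage lineage-restricted accessory blocks per lineage.
#' @param block_size genes per lineage block.
#' @param p_in carriage probability of a lineage block inside its lineage.
#' @param p_leak carriage probability outside the lineage.
#' @param n_mge mobile-element blocks (lineage-independent).
#' @param mge_size genes per mobile element.
#' @param p_mge_range per-element carriage probability drawn uniformly from
#'   this interval, once per element.
#' @param n_singletons genes placed in exactly one genome.
#' @param seed integer seed.
#' @return object of class `synthetic_pangenome_config`.
#' @export
synthetic_pangenome_config <- function(n_lineages = 3,
                                       genomes_per_lineage = 20,
                                       n_core = 200,
                                       blocks_per_lineage = 3,
                                       block_size = 10,
                                       p_in = 0.95,
                                       p_leak = 0.02,
                                       n_mge = 4,
                                       mge_size = 8,
                                       p_mge_range = c(0.05, 0.4),
                                       n_singletons = 30,
                                       seed = 1L) {
  probs <- c(p_in, p_leak, p_mge_range)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  counts <- c(n_lineages, genomes_per_lineage, n_core, blocks_per_lineage,
              block_size, n_mge, mge_size, n_singletons)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (n_lineages < 1) stop("need at least one lineage")
  if (genomes_per_lineage < 2) stop("need at least 2 genomes per lineage")
  structure(list(n_lineages = n_lineages,
                 genomes_per_lineage = genomes_per_lineage,
                 n_core = n_core, blocks_per_lineage = blocks_per_lineage,
                 block_size = block_size, p_in = p_in, p_leak = p_leak,
                 n_mge = n_mge, mge_size = mge_size,
                 p_mge_range = p_mge_range, n_singletons = n_singletons,
                 seed = as.integer(seed)),
            class = "synthetic_pangenome_config")
}

#' Simulate a synthetic pangenome
#'
#' Generates the presence/absence matrix, genome metadata (lineage, plus a
#' host label that splits the first lineage across two hosts), per-genome
#' circular gene orders, and the planted truth (genome lineages, gene block
#' labels). Sampling order, given the seed: (1) block-splice loci on the
#' core backbone, (2) lineage-block carriage per genome x block, (3) one
#' carriage probability per mobile element then carriage per genome x
#' element, (4) host genome of each singleton gene. Identical configs and
#' seeds therefore give bit-identical datasets.
#'
#' @param config a [synthetic_pangenome_config()] (or arguments passed to
#'   it via `...`).
#' @param ... used to build a config when `config` is missing.
#' @return object of class `synthetic_pangenome`: list with `matrix`
#'   ([gpa_matrix()]), `metadata` (`metadata_table`), `orders`
#'   ([gene_orders()]), `truth` (list: `genome_lineage`, `gene_block`) and
#'   `config`.
#' @export
simulate_pangenome <- function(config = NULL, ...) {
  if (is.null(config)) config <- synthetic_pangenome_config(...)
  stopifnot(inherits(config, "synthetic_pangenome_config"))
  cfg <- config
  set.seed(cfg$seed)

  lineages <- sprintf("L%d", seq_len(cfg$n_lineages))
  genomes <- as.vector(vapply(lineages, function(l)
    sprintf("%s_g%02d", l, seq_len(cfg$genomes_per_lineage)),
    character(cfg$genomes_per_lineage)))
  genome_lineage <- stats::setNames(
    rep(lineages, each = cfg$genomes_per_lineage), genomes)

  core_genes <- sprintf("core%04d", seq_len(cfg$n_core))
  block_ids <- as.vector(t(outer(lineages, seq_len(cfg$blocks_per_lineage),
                                 function(l, b) sprintf("%s.B%d", l, b))))
  block_genes <- lapply(block_ids, function(b)
    sprintf("%s.G%02d", b, seq_len(cfg$block_size)))
  names(block_genes) <- block_ids
  mge_ids <- if (cfg$n_mge > 0) sprintf("MGE%d", seq_len(cfg$n_mge))
             else character(0)
  mge_genes <- lapply(mge_ids, function(m)
    sprintf("%s.G%02d", m, seq_len(cfg$mge_size)))
  names(mge_genes) <- mge_ids
  singleton_genes <- if (cfg$n_singletons > 0)
    sprintf("sing%03d", seq_len(cfg$n_singletons)) else character(0)

  all_blocks <- c(block_ids, mge_ids)
  n_blocks <- length(all_blocks)
  # (1) distinct splice loci: block i sits between core locus[i] and its
  # successor on the circular backbone
  loci <- if (n_blocks > 0) {
    if (cfg$n_core < n_blocks) stop("need at least one core gene per block")
    sort(sample.int(cfg$n_core, n_blocks))
  } else integer(0)
  names(loci) <- all_blocks

  n_genomes <- length(genomes)
  genes <- c(core_genes, unlist(block_genes, use.names = FALSE),
             unlist(mge_genes, use.names = FALSE), singleton_genes)
  m <- matrix(0L, n_genomes, length(genes),
              dimnames = list(genomes, genes))
  m[, core_genes] <- 1L

  # (2) lineage block carriage
  carriage <- matrix(FALSE, n_genomes, n_blocks,
                     dimnames = list(genomes, all_blocks))
  for (b in block_ids) {
    lin <- sub("\\.B\\d+$", "", b)
    p <- ifelse(genome_lineage == lin, cfg$p_in, cfg$p_leak)
    carriage[, b] <- stats::runif(n_genomes) < p
    m[carriage[, b], block_genes[[b]]] <- 1L
  }
  # (3) mobile elements, lineage-independent
  for (mg in mge_ids) {
    p <- stats::runif(1, cfg$p_mge_range[1], cfg$p_mge_range[2])
    carriage[, mg] <- stats::runif(n_genomes) < p
    m[carriage[, mg], mge_genes[[mg]]] <- 1L
  }
  # (4) singletons
  if (cfg$n_singletons > 0) {
    hosts <- sample.int(n_genomes, cfg$n_singletons, replace = TRUE)
    for (i in seq_len(cfg$n_singletons)) {
      m[hosts[i], singleton_genes[i]] <- 1L
    }
  }

  # metadata: first lineage split across two host labels
  host <- sprintf("host_%s", genome_lineage)
  if (cfg$n_lineages >= 1) {
    first <- genome_lineage == lineages[1]
    idx <- which(first)
    half <- idx[seq_len(floor(length(idx) / 2))]
    host[first] <- sprintf("host_%s_a", lineages[1])
    host[half] <- sprintf("host_%s_b", lineages[1])
  }
  metadata <- as_metadata_table(data.frame(
    genome_id = genomes, lineage = unname(genome_lineage), host = host,
    stringsAsFactors = FALSE))

  # circular orders: core backbone with carried blocks spliced at their loci
  insertions <- split(all_blocks, loci)[as.character(sort(unique(loci)))]
  orders <- lapply(genomes, function(g) {
    parts <- character(0)
    prev <- 0L
    for (pos in sort(unique(loci))) {
      parts <- c(parts, core_genes[seq(prev + 1L, pos)])
      for (b in insertions[[as.character(pos)]]) {
        if (carriage[g, b]) {
          parts <- c(parts, if (b %in% block_ids) block_genes[[b]]
                     else mge_genes[[b]])
        }
      }
      prev <- pos
    }
    if (prev < cfg$n_core) {
      parts <- c(parts, core_genes[seq(prev + 1L, cfg$n_core)])
    }
    singles <- singleton_genes[m[g, singleton_genes] == 1L]
    parts <- c(parts, singles)  # noise genes appended at the terminus
    attr(parts, "circular") <- TRUE
    list(chromosome = parts)
  })
  names(orders) <- genomes
  orders <- lapply(orders, function(o) {
    attr(o$chromosome, "circular") <- TRUE
    o
  })

  gene_block <- c(
    stats::setNames(rep("core", length(core_genes)), core_genes),
    stats::setNames(rep(block_ids, each = cfg$block_size),
                    unlist(block_genes, use.names = FALSE)),
    stats::setNames(rep(mge_ids, each = cfg$mge_size),
                    unlist(mge_genes, use.names = FALSE)),
    stats::setNames(rep("singleton", length(singleton_genes)),
                    singleton_genes))

  structure(list(
    matrix = gpa_matrix(m, drop_empty_genes = FALSE),
    metadata = metadata,
    orders = gene_orders(orders),
    truth = list(genome_lineage = genome_lineage, gene_block = gene_block,
                 block_carriage = carriage),
    config = cfg), class = "synthetic_pangenome")
}

#' @export
print.synthetic_pangenome <- function(x, ...) {
  cat(sprintf("synthetic_pangenome: %d genomes (%d lineages) x %d genes, seed %d\n",
              nrow(x$matrix$values), x$config$n_lineages,
              ncol(x$matrix$values), x$config$seed))
  invisible(x)
}

#' Adjusted Rand Index between two labelled partitions
#'
#' @param a,b named label vectors over the same ids (order-independent).
#' @return ARI in [-1, 1]; 1 for identical partitions, ~0 for random ones.
#' @export
adjusted_rand_index <- function(a, b) {
  ids <- intersect(names(a), names(b))
  if (length(ids) < 2) stop("need at least two shared ids")
  ct <- table(as.character(a[ids]), as.character(b[ids]))
  nij <- sum(choose(ct, 2))
  ai <- sum(choose(rowSums(ct), 2))
  bj <- sum(choose(colSums(ct), 2))
  n2 <- choose(length(ids), 2)
  expected <- ai * bj / n2
  denom <- (ai + bj) / 2 - expected
  if (denom == 0) return(ifelse(nij == expected, 1, 0))
  (nij - expected) / denom
}

#' Pairwise F1 between a clustering and a reference partition
#'
#' Precision/recall over unordered id pairs: a pair is "predicted" when
#' co-clustered in `clusters`, "true" when co-labelled in `reference`.
#'
#' @param clusters,reference named label vectors over shared ids.
#' @return F1 in [0, 1].
#' @export
pairwise_f1 <- function(clusters, reference) {
  ids <- sort(intersect(names(clusters), names(reference)))
  if (length(ids) < 2) stop("need at least two shared ids")
  cl <- as.character(clusters[ids])
  ref <- as.character(reference[ids])
  pred <- outer(cl, cl, `==`)[upper.tri(diag(length(ids)))]
  true <- outer(ref, ref, `==`)[upper.tri(diag(length(ids)))]
  tp <- sum(pred & true)
  if (tp == 0) return(0)
  prec <- tp / sum(pred)
  rec <- tp / sum(true)
  2 * prec * rec / (prec + rec)
}

#' Recovery scores of clusterings against the planted truth
#'
#' @param dataset a `synthetic_pangenome`.
#' @param genome_clusters optional `cluster_assignment` over genomes;
#'   scored by Adjusted Rand Index against the planted lineages.
#' @param gene_clusters optional `cluster_assignment` over genes; scored by
#'   pairwise F1 against the planted blocks (core genes and singletons are
#'   excluded; genes missing from the assignment are ignored).
#' @return list with `lineage_ari` and/or `block_f1`.
#' @export
truth_metrics <- function(dataset, genome_clusters = NULL,
                          gene_clusters = NULL) {
  stopifnot(inherits(dataset, "synthetic_pangenome"))
  out <- list()
  if (!is.null(genome_clusters)) {
    out$lineage_ari <- adjusted_rand_index(
      stats::setNames(as.character(genome_clusters), names(genome_clusters)),
      dataset$truth$genome_lineage)
  }
  if (!is.null(gene_clusters)) {
    blocks <- dataset$truth$gene_block
    blocks <- blocks[!blocks %in% c("core", "singleton")]
    shared <- intersect(names(gene_clusters), names(blocks))
    out$block_f1 <- pairwise_f1(
      stats::setNames(as.character(gene_clusters)[match(shared, names(gene_clusters))],
                      shared),
      blocks[shared])
  }
  out
}

#' Write a synthetic dataset to plain-text files
#'
#' Writes `matrix.rtab`, `metadata.tsv`, `orders.tsv` (genome, contig,
#' position, gene, circular) and `truth.tsv` into a directory.
#'
#' @param dataset a `synthetic_pangenome`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_synthetic_pangenome <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_pangenome"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_rtab(dataset$matrix, file.path(dir, "matrix.rtab"))
  utils::write.table(as.data.frame(dataset$metadata),
                     file.path(dir, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  rows <- list()
  for (g in names(dataset$orders)) {
    for (ct_name in names(dataset$orders[[g]])) {
      ct <- dataset$orders[[g]][[ct_name]]
      rows[[length(rows) + 1L]] <- data.frame(
        genome = g, contig = ct_name, position = seq_along(ct), gene = ct,
        circular = contig_circular(ct), stringsAsFactors = FALSE)
    }
  }
  utils::write.table(do.call(rbind, rows), file.path(dir, "orders.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- rbind(
    data.frame(id = names(dataset$truth$genome_lineage), kind = "genome",
               label = unname(dataset$truth$genome_lineage)),
    data.frame(id = names(dataset$truth$gene_block), kind = "gene",
               label = unname(dataset$truth$gene_block)))
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
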