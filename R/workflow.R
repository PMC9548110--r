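# End-to-end "three graphs" workflow: genome-genome similarity, gene-gene
# co-occurrence, gene synteny; clustering; enrichment; profiles; exports.

#' Resolve fractional frequency cutoffs to integer genome-count weights
#'
#' The low cutoff `W_lo = ceiling(low_frac * n)` is the smallest weight NOT
#' below the fraction, so "weight < W_lo" removes edges below it; the high
#' cutoff `W_hi = floor(high_frac * n)` is the largest weight NOT above the
#' fraction, so "weight > W_hi" selects edges exceeding it. For n = 778
#' genomes this reproduces the 1%/99% cutoffs 8 and 770.
#'
#' @param n_genomes population size.
#' @param low_frac,high_frac fractions in [0, 1], `low_frac <= high_frac`.
#' @return named numeric vector `c(low = W_lo, high = W_hi)`.
#' @export
resolve_fraction_cutoffs <- function(n_genomes, low_frac, high_frac) {
  stopifnot(low_frac >= 0, high_frac <= 1, low_frac <= high_frac)
  c(low = ceiling(low_frac * n_genomes),
    high = floor(high_frac * n_genomes))
}

#' Default workflow configuration
#'
#' Parameters follow the published defaults of the workflow: genome graphs
#' are Jaccard over accessory content thresholded strictly then k-NN
#' sparsified and MCL-clustered; gene graphs are frequency-filtered
#' (1%/99%), thresholded at JSC > 0.55 and MCL-clustered; synteny graphs are
#' simplified by low-weight edge removal, largest-component selection and
#' contraction of edges conserved in > `contract_frac` of genomes.
#'
#' @param ... overrides of the defaults.
#' @return nested list of parameter blocks.
#' @export
workflow_config <- function(...) {
  cfg <- list(
    seed = 1L,
    genome_graph = list(metric = "jaccard", accessory_only = TRUE,
                        core_fraction = 1, min_weight = 0.5, knn = 10,
                        inflation = 2.0),
    gene_graph = list(metric = "jaccard", min_frac = 0.01, max_frac = 0.99,
                      min_weight = 0.55, knn = NULL, inflation = 1.5),
    synteny = list(low_frac = 0.01, contract_frac = 0.99,
                   louvain_granularity = 0.4, min_component = 1),
    enrichment = list(attribute = "lineage", alpha = 0.05, adjust = "BH"),
    profiles = list(order_by = NULL))
  modifyList(cfg, list(...))
}

#' Run the full three-graph workflow
#'
#' Builds, filters and clusters the genome-genome, gene-gene and synteny
#' graphs; runs the cluster-vs-metadata enrichment; computes gene-cluster
#' profiles; and writes every artifact (".layout", GraphML, TSV tables,
#' transform logs) plus a manifest with parameters and content hashes into
#' `out_dir`. Any stage failure aborts naming the stage.
#'
#' @param matrix a [gpa_matrix()].
#' @param metadata a `metadata_table` over the matrix's genomes.
#' @param orders a [gene_orders()] object (for the synteny graph), or NULL
#'   to skip synteny.
#' @param out_dir output directory.
#' @param config a [workflow_config()].
#' @return the manifest, invisibly (list; also written as manifest.json).
#' @export
run_workflow <- function(matrix, metadata, orders, out_dir,
                         config = workflow_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(parameters = config, artifacts = list(), stages = list())
  n_genomes <- nrow(matrix$values)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("workflow stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  emit <- function(obj, name, kind) {
    paths <- character(0)
    if (kind == "graph") {
      p1 <- file.path(out_dir, paste0(name, ".layout"))
      p2 <- file.path(out_dir, paste0(name, ".graphml"))
      p3 <- file.path(out_dir, paste0(name, ".edges.tsv"))
      write_layout(obj, p1)
      export_graph(obj, p2, "graphml")
      export_graph(obj, p3, "edge_tsv")
      p4 <- file.path(out_dir, paste0(name, ".transforms.tsv"))
      write_transform_log(obj, p4)
      paths <- c(p1, p2, p3, p4)
    } else if (kind == "clusters") {
      p <- file.path(out_dir, paste0(name, ".tsv"))
      write_clusters(obj, p)
      paths <- p
    } else if (kind == "table") {
      p <- file.path(out_dir, paste0(name, ".tsv"))
      utils::write.table(obj, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      paths <- p
    }
    for (p in paths) {
      manifest$artifacts[[basename(p)]] <<- list(
        path = basename(p), kind = kind,
        md5 = unname(tools::md5sum(p)))
    }
    invisible(obj)
  }

  # --- genome-genome graph -------------------------------------------------
  gg_cfg <- config$genome_graph
  genome_graph <- stage("genome_graph", {
    sim <- pairwise_similarity(matrix, "genomes", gg_cfg$metric,
                               accessory_only = gg_cfg$accessory_only,
                               core_fraction = gg_cfg$core_fraction)
    g <- similarity_graph(sim, min_weight = gg_cfg$min_weight)
    if (!is.null(gg_cfg$knn)) g <- knn_sparsify(g, gg_cfg$knn)
    g
  })
  genome_clusters <- stage("genome_clustering",
                           mcl_cluster(genome_graph, gg_cfg$inflation))
  genome_graph <- igraph::set_vertex_attr(
    genome_graph, "cluster",
    value = as.integer(genome_clusters[igraph::V(genome_graph)$name]))
  for (a in setdiff(colnames(metadata), "genome_id")) {
    v <- metadata_attribute(metadata, a)
    genome_graph <- igraph::set_vertex_attr(
      genome_graph, a, value = unname(v[igraph::V(genome_graph)$name]))
  }
  emit(genome_graph, "genome_graph", "graph")
  emit(genome_clusters, "genome_clusters", "clusters")

  # --- gene-gene co-occurrence graph ---------------------------------------
  ge_cfg <- config$gene_graph
  gene_graph <- stage("gene_graph", {
    filt <- filter_nodes_by_frequency(matrix, min_frac = ge_cfg$min_frac,
                                      max_frac = ge_cfg$max_frac)
    sim <- pairwise_similarity(filt, "genes", ge_cfg$metric)
    g <- similarity_graph(sim, min_weight = ge_cfg$min_weight)
    if (!is.null(ge_cfg$knn)) g <- knn_sparsify(g, ge_cfg$knn)
    g
  })
  gene_clusters <- stage("gene_clustering",
                         mcl_cluster(gene_graph, ge_cfg$inflation))
  gene_graph <- igraph::set_vertex_attr(
    gene_graph, "cluster",
    value = as.integer(gene_clusters[igraph::V(gene_graph)$name]))
  emit(gene_graph, "gene_graph", "graph")
  emit(gene_clusters, "gene_clusters", "clusters")

  # --- synteny graph -------------------------------------------------------
  if (!is.null(orders)) {
    sy_cfg <- config$synteny
    cut <- resolve_fraction_cutoffs(n_genomes, sy_cfg$low_frac,
                                    sy_cfg$contract_frac)
    synteny <- stage("synteny_graph", {
      g <- build_synteny_graph(orders)
      g <- filter_edges_min_weight(g, cut[["low"]] - 1)  # drop weight < W_lo
      g <- keep_largest_component(g)
      g <- contract_core_edges(g, cut[["high"]])
      overlay_clusters(g, gene_clusters)
    })
    synteny_clusters <- stage("synteny_clustering",
                              louvain_cluster(synteny,
                                              sy_cfg$louvain_granularity,
                                              seed = config$seed))
    synteny <- igraph::set_vertex_attr(
      synteny, "louvain_cluster",
      value = as.integer(synteny_clusters[igraph::V(synteny)$name]))
    emit(synteny, "synteny_graph", "graph")
    emit(synteny_clusters, "synteny_clusters", "clusters")
    manifest$stages$synteny <- list(low_weight_cutoff = unname(cut[["low"]]),
                                    contract_cutoff = unname(cut[["high"]]))
  }

  # --- enrichment: genome clusters vs metadata -----------------------------
  en_cfg <- config$enrichment
  enrichment <- stage("enrichment", {
    enrichment_analysis(genome_clusters,
                        metadata_attribute(metadata, en_cfg$attribute),
                        alpha = en_cfg$alpha, adjust = en_cfg$adjust)
  })
  emit(enrichment, "enrichment", "table")

  # --- gene-cluster profiles ----------------------------------------------
  profiles <- stage("profiles", {
    gene_cluster_profiles(matrix, gene_clusters, genome_order = metadata,
                          order_by = config$profiles$order_by)
  })
  prof_tab <- data.frame(
    cluster = rep(rownames(profiles$proportions),
                  times = ncol(profiles$proportions)),
    genome = rep(colnames(profiles$proportions),
                 each = nrow(profiles$proportions)),
    proportion = as.vector(profiles$proportions))
  emit(prof_tab, "profiles", "table")

  manifest$n_genomes <- n_genomes
  manifest$n_genes <- ncol(matrix$values)
  json <- jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA)
  writeLines(json, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}
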