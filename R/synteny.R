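# Gene synteny graphs: nodes are gene families, edge weights count the
# genomes in which two families are observed adjacent on a replicon.

#' Gene orders container
#'
#' Per-genome, per-contig ordered lists of gene family ids.
#'
#' @param orders named list (genome id) of lists of contigs; each contig is a
#'   character vector of family ids. A contig may carry a `circular`
#'   attribute (logical); contigs are linear by default since draft
#'   assemblies carry no standard circularity marker.
#' @return object of class `gene_orders`.
#' @export
gene_orders <- function(orders) {
  stopifnot(is.list(orders), !is.null(names(orders)))
  for (g in names(orders)) {
    stopifnot(is.list(orders[[g]]))
    if (!length(orders[[g]])) stop("genome ", g, " has no contigs")
    for (ct in orders[[g]]) {
      if (!is.character(ct) || !length(ct)) {
        stop("genome ", g, ": contigs must be non-empty character vectors")
      }
    }
  }
  structure(orders, class = "gene_orders")
}

contig_circular <- function(contig) isTRUE(attr(contig, "circular"))

#' Derive per-genome gene orders from GFF3 annotation files
#'
#' Features of the requested types are sorted per contig by start coordinate
#' (GFF3, 1-based; ties broken by end then feature id); strand is ignored for
#' ordering and features on different contigs are never adjacent. Feature ids
#' are mapped to gene families through `map`; unmapped features are skipped
#' with a counted warning.
#'
#' @param gff_paths named character vector of GFF3 files, names = genome ids
#'   (basenames used when unnamed).
#' @param map named character vector: feature/allele id -> gene family id.
#' @param feature_types GFF3 types to use (default CDS and gene).
#' @param circular logical: treat every contig as circular (config-supplied;
#'   GFF3 itself has no circularity marker).
#' @return a [gene_orders()] object.
#' @export
gene_orders_from_gff <- function(gff_paths, map,
                                 feature_types = c("CDS", "gene"),
                                 circular = FALSE) {
  if (is.null(names(gff_paths))) {
    names(gff_paths) <- sub("\\.gff3?$", "", basename(gff_paths))
  }
  skipped <- 0L
  out <- lapply(names(gff_paths), function(genome) {
    feats <- read_gff_features(gff_paths[[genome]], feature_types)
    feats <- feats[order(feats$seqid, feats$start, feats$end, feats$id), ]
    mapped <- feats$id %in% names(map)
    skipped <<- skipped + sum(!mapped)
    feats <- feats[mapped, , drop = FALSE]
    if (!nrow(feats)) {
      stop("genome ", genome, ": no features could be mapped to families")
    }
    contigs <- lapply(split(unname(map[feats$id]), feats$seqid), function(x) {
      attr(x, "circular") <- circular
      x
    })
    contigs[order(names(contigs))]
  })
  if (skipped > 0) {
    warning(skipped, " feature(s) absent from the family map were skipped")
  }
  names(out) <- names(gff_paths)
  gene_orders(out)
}

# Minimal GFF3 feature reader; uses rtracklayer when available, else a plain
# column parse (format is tab-delimited with ID=... attributes).
read_gff_features <- function(path, feature_types) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[as.character(gr$type) %in% feature_types]
    id <- as.character(gr$ID)
    if (anyNA(id) && "locus_tag" %in% colnames(S4Vectors::mcols(gr))) {
      lt <- as.character(gr$locus_tag)
      id[is.na(id)] <- lt[is.na(id)]
    }
    return(data.frame(seqid = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr),
                      end = GenomicRanges::end(gr),
                      id = id, stringsAsFactors = FALSE))
  }
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  parts <- parts[lengths(parts) >= 9]
  keep <- vapply(parts, function(p) p[3] %in% feature_types, logical(1))
  parts <- parts[keep]
  id <- vapply(parts, function(p) {
    m <- regmatches(p[9], regexec("(?:^|;)ID=([^;]+)", p[9]))[[1]]
    if (length(m) == 2) m[2] else NA_character_
  }, character(1))
  data.frame(seqid = vapply(parts, `[`, character(1), 1),
             start = as.integer(vapply(parts, `[`, character(1), 4)),
             end = as.integer(vapply(parts, `[`, character(1), 5)),
             id = id, stringsAsFactors = FALSE)
}

#' Build the gene synteny graph from per-genome gene orders
#'
#' Each genome contributes its set of unordered adjacent family pairs
#' (circular contigs close the last-first adjacency). A given pair counts at
#' most once per genome, so edge weights are genome counts and the
#' ">99% of genomes" contraction rule is well defined. Self-adjacencies
#' (tandem repeats of one family) are dropped and counted in a message.
#' Nodes carry `frequency` (genomes containing the family), `member_genes`
#' (initialised to the family itself) and `multiplicity` (1).
#'
#' @param orders a [gene_orders()] object.
#' @return weighted igraph (the synteny graph).
#' @export
build_synteny_graph <- function(orders) {
  stopifnot(inherits(orders, "gene_orders"))
  pair_counts <- new.env(parent = emptyenv())
  freq <- new.env(parent = emptyenv())
  self_adj <- 0L
  for (genome in names(orders)) {
    fams <- unique(unlist(orders[[genome]], use.names = FALSE))
    for (f in fams) {
      freq[[f]] <- (if (is.null(freq[[f]])) 0L else freq[[f]]) + 1L
    }
    pairs <- character(0)
    for (contig in orders[[genome]]) {
      n <- length(contig)
      if (n < 2 && !(contig_circular(contig) && n >= 2)) next
      a <- contig
      b <- c(contig[-1], if (contig_circular(contig)) contig[1])
      if (length(b) < length(a)) a <- a[-n]
      loops <- a == b
      self_adj <- self_adj + sum(loops)
      a2 <- pmin(a[!loops], b[!loops])
      b2 <- pmax(a[!loops], b[!loops])
      pairs <- c(pairs, paste(a2, b2, sep = "\r"))
    }
    for (p in unique(pairs)) {  # cap: once per genome
      pair_counts[[p]] <- (if (is.null(pair_counts[[p]])) 0L
                           else pair_counts[[p]]) + 1L
    }
  }
  if (self_adj > 0) {
    message("dropped ", self_adj, " tandem self-adjacenc",
            if (self_adj == 1) "y" else "ies")
  }
  keys <- ls(pair_counts)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  edges <- data.frame(
    from = vapply(parts, `[`, character(1), 1),
    to = vapply(parts, function(p) p[2], character(1)),
    weight = vapply(keys, function(k) as.numeric(pair_counts[[k]]),
                    numeric(1)),
    stringsAsFactors = FALSE)
  fams_all <- sort(ls(freq))
  g <- weighted_graph(edges, nodes = fams_all)
  g <- igraph::set_vertex_attr(
    g, "frequency",
    value = vapply(igraph::V(g)$name, function(f) as.numeric(freq[[f]]),
                   numeric(1)))
  g <- igraph::set_vertex_attr(g, "member_genes",
                               value = as.list(igraph::V(g)$name))
  g <- igraph::set_vertex_attr(g, "multiplicity",
                               value = rep(1L, igraph::vcount(g)))
  igraph::graph_attr(g, "n_genomes") <- length(orders)
  g
}

#' Build a synteny graph directly from an edge list
#'
#' For PIRATE-style `.edges` input (after [collapse_alleles_to_families()]).
#' Node frequencies are not derivable from an edge list alone and may be
#' supplied separately.
#'
#' @param edges data.frame with columns `from`, `to`, `weight`.
#' @param frequency optional named numeric vector of per-family genome
#'   counts.
#' @param n_genomes optional genome count (recorded; weights above it are
#'   clamped with a warning).
#' @return weighted igraph.
#' @export
synteny_graph_from_edges <- function(edges, frequency = NULL,
                                     n_genomes = NULL) {
  if (!is.null(n_genomes) && any(edges$weight > n_genomes)) {
    warning("clamping ", sum(edges$weight > n_genomes),
            " edge weight(s) to the genome count ", n_genomes)
    edges$weight <- pmin(edges$weight, n_genomes)
  }
  g <- weighted_graph(edges)
  if (!is.null(frequency)) {
    g <- igraph::set_vertex_attr(
      g, "frequency",
      value = as.numeric(frequency[igraph::V(g)$name]))
  }
  g <- igraph::set_vertex_attr(g, "member_genes",
                               value = as.list(igraph::V(g)$name))
  g <- igraph::set_vertex_attr(g, "multiplicity",
                               value = rep(1L, igraph::vcount(g)))
  if (!is.null(n_genomes)) igraph::graph_attr(g, "n_genomes") <- n_genomes
  g
}

#' Overlay gene-cluster labels onto a synteny graph
#'
#' Maps clustering information from the gene-gene co-occurrence graph onto
#' the synteny network. Plain nodes receive the cluster label of their
#' family; merged nodes (post-contraction) receive the multiset of member
#' labels (attribute `<name>_members`) and a majority label (ties broken by
#' the smaller label; `"unassigned"` loses ties to real labels). Families
#' absent from the assignment are labelled `"unassigned"`.
#'
#' @param graph synteny graph.
#' @param assignment a [cluster_assignment][mcl_cluster()] over gene family
#'   ids (or any named vector of labels).
#' @param attribute_name node attribute to write (default `"gene_cluster"`).
#' @return graph with cluster attributes added.
#' @export
overlay_clusters <- function(graph, assignment,
                             attribute_name = "gene_cluster") {
  labels <- stats::setNames(as.character(assignment), names(assignment))
  members <- if ("member_genes" %in% igraph::vertex_attr_names(graph)) {
    igraph::V(graph)$member_genes
  } else {
    as.list(igraph::V(graph)$name)
  }
  member_labels <- lapply(members, function(ms) {
    l <- labels[ms]
    l[is.na(l)] <- "unassigned"
    unname(l)
  })
  majority <- vapply(member_labels, function(l) {
    tab <- sort(table(l), decreasing = TRUE)
    top <- names(tab)[tab == max(tab)]
    real <- setdiff(top, "unassigned")
    if (length(real)) sort(real)[1] else "unassigned"
  }, character(1))
  graph <- igraph::set_vertex_attr(graph, attribute_name, value = majority)
  graph <- igraph::set_vertex_attr(
    graph, paste0(attribute_name, "_members"),
    value = vapply(member_labels, paste, character(1), collapse = ";"))
  graph
}
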