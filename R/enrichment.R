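# Cluster-metadata enrichment (Fisher exact, BH-adjusted) and gene-cluster
# distribution profiles.

#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' Conditional on both margins, sums the hypergeometric probabilities of all
#' tables whose probability does not exceed that of the observed table
#' (within a small relative slack for ties at equal probability). Degenerate
#' margins give p = 1.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2, 2))) stop("expected a 2x2 table")
  if (anyNA(tab) || any(tab < 0) || any(tab != round(tab))) {
    stop("counts must be non-negative integers")
  }
  a <- tab[1, 1]
  m1 <- tab[1, 1] + tab[1, 2]   # white balls
  m2 <- tab[2, 1] + tab[2, 2]   # black balls
  n1 <- tab[1, 1] + tab[2, 1]   # drawn
  lo <- max(0, n1 - m2)
  hi <- min(n1, m1)
  k <- lo:hi
  probs <- stats::dhyper(k, m1, m2, n1)
  p_obs <- stats::dhyper(a, m1, m2, n1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(p, 1)
}

#' Pairwise Fisher enrichment between two categorical node attributes
#'
#' Tests every (value of `attr_a`) x (value of `attr_b`) pair over the shared
#' node universe with a two-sided Fisher exact test on the 2x2 membership
#' table, then adjusts across all pairs tested in the call
#' (Benjamini-Hochberg by default). The typical use is network clusters
#' against a metadata variable (e.g. MCL cluster x clonal complex).
#'
#' @param attr_a,attr_b named vectors (node -> category); a
#'   `cluster_assignment` works directly. Nodes must overlap; only nodes
#'   present in both vectors form the universe. Unless `include_na`, nodes
#'   whose value is the missing sentinel `"NA"` are excluded.
#' @param alpha significance level applied to the adjusted p-values.
#' @param adjust `"BH"` (default) or `"bonferroni"`.
#' @param include_na keep the `"NA"` sentinel category in the universe.
#' @return data.frame with one row per pair: `value_a`, `value_b`, the 2x2
#'   counts (`n_ab`, `n_a_only`, `n_b_only`, `n_neither`), `odds_ratio`,
#'   `p`, `adj_p`, `significant`; plus an `any_significant` attribute
#'   (per value of `attr_a`, is it associated with at least one value_b).
#' @export
enrichment_analysis <- function(attr_a, attr_b, alpha = 0.05,
                                adjust = c("BH", "bonferroni"),
                                include_na = FALSE) {
  adjust <- match.arg(adjust)
  a <- stats::setNames(as.character(attr_a), names(attr_a))
  b <- stats::setNames(as.character(attr_b), names(attr_b))
  universe <- intersect(names(a), names(b))
  if (!include_na) {
    universe <- universe[a[universe] != "NA" & b[universe] != "NA"]
  }
  if (!length(universe)) stop("empty node universe")
  a <- a[universe]
  b <- b[universe]
  n <- length(universe)
  vals_a <- sort(unique(a))
  vals_b <- sort(unique(b))
  grid <- expand.grid(value_a = vals_a, value_b = vals_b,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    in_a <- a == grid$value_a[i]
    in_b <- b == grid$value_b[i]
    n_ab <- sum(in_a & in_b)
    n_a_only <- sum(in_a & !in_b)
    n_b_only <- sum(!in_a & in_b)
    n_neither <- n - n_ab - n_a_only - n_b_only
    tab <- matrix(c(n_ab, n_a_only, n_b_only, n_neither), 2, byrow = TRUE)
    or <- (n_ab * n_neither) / (n_a_only * n_b_only)
    data.frame(value_a = grid$value_a[i], value_b = grid$value_b[i],
               n_ab = n_ab, n_a_only = n_a_only, n_b_only = n_b_only,
               n_neither = n_neither, odds_ratio = or,
               p = fisher_exact_2x2(tab), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- stats::p.adjust(out$p, method = if (adjust == "BH") "BH"
                               else "bonferroni")
  out$significant <- out$adj_p < alpha
  any_sig <- vapply(vals_a, function(v) any(out$significant[out$value_a == v]),
                    logical(1))
  attr(out, "any_significant") <- stats::setNames(any_sig, vals_a)
  attr(out, "universe_size") <- n
  out
}

#' Gene-cluster distribution profiles
#'
#' For each gene cluster and genome, the proportion of the cluster's genes
#' present in that genome (each bar of a profile plot). Genomes are ordered
#' by the supplied sort keys, typically lineage labels such as clonal
#' complex then host.
#'
#' @param matrix a [gpa_matrix()].
#' @param assignment a `cluster_assignment` over (a subset of) the matrix's
#'   gene ids.
#' @param genome_order optional character vector of genome ids, or a
#'   `metadata_table` plus `order_by` attribute names used as sort keys.
#' @param order_by attribute names in `genome_order` (when it is a
#'   metadata table) to sort genomes by, in priority order.
#' @return object of class `gene_cluster_profile`: a list with `proportions`
#'   (clusters x genomes matrix) and `genomes` (the ordering used).
#' @export
gene_cluster_profiles <- function(matrix, assignment, genome_order = NULL,
                                  order_by = NULL) {
  stopifnot(is_gpa_matrix(matrix))
  genes <- intersect(names(assignment), gene_ids(matrix))
  if (!length(genes)) stop("assignment covers no gene in the matrix")
  labels <- unclass(assignment)[genes]
  genomes <- genome_ids(matrix)
  if (inherits(genome_order, "metadata_table")) {
    md <- genome_order[match(genomes, genome_order$genome_id), , drop = FALSE]
    keys <- if (is.null(order_by)) setdiff(colnames(md), "genome_id")
            else order_by
    ord <- do.call(order, c(unname(as.list(md[, keys, drop = FALSE])),
                            list(genomes)))
    genomes <- genomes[ord]
  } else if (!is.null(genome_order)) {
    if (!all(genomes %in% genome_order)) {
      stop("genome_order must contain every genome in the matrix")
    }
    genomes <- genome_order[genome_order %in% genomes]
  }
  x <- matrix$values[genomes, , drop = FALSE]
  clusters <- sort(unique(labels))
  prop <- t(vapply(clusters, function(cl) {
    members <- genes[labels == cl]
    rowSums(x[, members, drop = FALSE]) / length(members)
  }, numeric(length(genomes))))
  dimnames(prop) <- list(as.character(clusters), genomes)
  structure(list(proportions = prop, genomes = genomes),
            class = "gene_cluster_profile")
}

#' @export
print.gene_cluster_profile <- function(x, ...) {
  cat(sprintf("gene_cluster_profile: %d clusters x %d genomes\n",
              nrow(x$proportions), ncol(x$proportions)))
  invisible(x)
}

#' Plot gene-cluster distribution profiles
#'
#' One bar panel per cluster: bar height is the proportion of the cluster's
#' genes present in each genome, genomes in the profile's order, with
#' optional categorical annotation tracks under the axis. The numeric TSV
#' twin (`<path>.tsv`, long format: cluster, genome, proportion) is always
#' written; figures themselves are presentation output, not a test surface.
#'
#' @param profile a `gene_cluster_profile`.
#' @param path output figure file (`.png` or `.svg` decides the device).
#' @param annotations optional `metadata_table` supplying the tracks.
#' @param tracks attribute names to draw as tracks (default: all).
#' @return the TSV path, invisibly.
#' @export
plot_profiles <- function(profile, path, annotations = NULL, tracks = NULL) {
  stopifnot(inherits(profile, "gene_cluster_profile"))
  prop <- profile$proportions
  if (any(prop < 0 | prop > 1)) stop("proportions must lie in [0, 1]")
  tsv <- paste0(path, ".tsv")
  long <- data.frame(
    cluster = rep(rownames(prop), times = ncol(prop)),
    genome = rep(colnames(prop), each = nrow(prop)),
    proportion = as.vector(prop))
  long <- long[order(long$cluster, match(long$genome, profile$genomes)), ]
  utils::write.table(long, tsv, sep = "\t", quote = FALSE, row.names = FALSE)

  track_values <- list()
  if (!is.null(annotations)) {
    if (is.null(tracks)) tracks <- setdiff(colnames(annotations), "genome_id")
    for (a in tracks) {
      v <- metadata_attribute(annotations, a)[profile$genomes]
      v[is.na(v)] <- "NA"
      track_values[[a]] <- v
    }
  }
  n_cl <- nrow(prop)
  n_tracks <- length(track_values)
  dev <- if (grepl("\\.svg$", path)) grDevices::svg else grDevices::png
  args <- if (identical(dev, grDevices::png)) {
    list(filename = path, width = 1200,
         height = 220 * n_cl + 40 * n_tracks + 60)
  } else {
    list(filename = path, width = 10,
         height = 1.8 * n_cl + 0.4 * n_tracks + 0.6)
  }
  do.call(dev, args)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(n_cl + (n_tracks > 0), 1),
                mar = c(1.2, 4, 1.5, 1))
  for (cl in rownames(prop)) {
    graphics::barplot(prop[cl, ], ylim = c(0, 1), border = NA,
                      names.arg = rep("", ncol(prop)), space = 0,
                      ylab = "proportion", main = paste("Cluster", cl))
  }
  if (n_tracks > 0) {
    graphics::plot.new()
    graphics::plot.window(xlim = c(0, ncol(prop)), ylim = c(0, n_tracks))
    for (i in seq_len(n_tracks)) {
      v <- track_values[[i]]
      lev <- sort(unique(v))
      cols <- grDevices::hcl.colors(max(length(lev), 2), "Dark 3")
      graphics::rect(seq_along(v) - 1, n_tracks - i, seq_along(v),
                     n_tracks - i + 0.8,
                     col = cols[match(v, lev)], border = NA)
      graphics::mtext(names(track_values)[i], side = 2, las = 1,
                      at = n_tracks - i + 0.4, cex = 0.7)
    }
  }
  invisible(tsv)
}
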