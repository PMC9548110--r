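#' Gene presence/absence matrix
#'
#' The central container of the package: a binary genomes x gene-families
#' matrix. Rows are genomes, columns are gene families; a cell is 1 when at
#' least one member of the family is present in that genome. It is the single
#' source for both similarity orientations: genome-genome graphs are computed
#' over rows, gene-gene co-occurrence graphs over columns.
#'
#' @param values binary matrix (0/1) with genomes as rows and gene families as
#'   columns; must carry unique row and column names.
#' @param gene_annotations optional named character vector mapping gene family
#'   ids to product/description strings.
#' @param identity_threshold optional percent identity at which the families
#'   were called (recorded, not interpreted).
#' @param drop_empty_genes drop all-zero gene columns with a message (the
#'   default, enforcing the loading invariant that a family must occur
#'   somewhere); `FALSE` keeps them, for matrices constructed in code (e.g.
#'   a simulated mobile element that happened to draw zero carriers).
#' @return an object of class `gpa_matrix`.
#' @export
gpa_matrix <- function(values, gene_annotations = NULL,
                       identity_threshold = NULL, drop_empty_genes = TRUE) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("gpa_matrix values must have genome row names and gene column names")
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate genome identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate gene identifiers: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  }
  storage.mode(values) <- "integer"
  if (anyNA(values) || !all(values %in% c(0L, 1L))) {
    stop("gpa_matrix values must be binary (0/1)")
  }
  empty <- colSums(values) == 0L
  if (any(empty) && drop_empty_genes) {
    message("dropping ", sum(empty), " gene families absent from every genome")
    values <- values[, !empty, drop = FALSE]
  }
  if (!is.null(gene_annotations)) {
    gene_annotations <- gene_annotations[names(gene_annotations) %in%
                                           colnames(values)]
  }
  structure(
    list(values = values,
         gene_annotations = gene_annotations,
         identity_threshold = identity_threshold),
    class = "gpa_matrix")
}

#' @export
print.gpa_matrix <- function(x, ...) {
  v <- x$values
  core <- sum(colSums(v) == nrow(v))
  cat(sprintf("gpa_matrix: %d genomes x %d gene families (%d core, %d accessory)\n",
              nrow(v), ncol(v), core, ncol(v) - core))
  if (!is.null(x$identity_threshold)) {
    cat(sprintf("  identity threshold: %s%%\n", x$identity_threshold))
  }
  invisible(x)
}

#' @rdname gpa_matrix
#' @param x object to test or coerce.
#' @export
is_gpa_matrix <- function(x) inherits(x, "gpa_matrix")

#' Genome and gene identifiers of a presence/absence matrix
#'
#' @param m a [gpa_matrix()].
#' @return character vector of identifiers.
#' @export
genome_ids <- function(m) {
  stopifnot(is_gpa_matrix(m))
  rownames(m$values)
}

#' @rdname genome_ids
#' @export
gene_ids <- function(m) {
  stopifnot(is_gpa_matrix(m))
  colnames(m$values)
}

#' Per-family genome frequencies
#'
#' Number of genomes carrying each gene family (the column sums).
#'
#' @param m a [gpa_matrix()].
#' @return named integer vector over gene families.
#' @export
gene_frequencies <- function(m) {
  stopifnot(is_gpa_matrix(m))
  colSums(m$values)
}
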