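# Readers for the standard pangenome-tool outputs.

#' Read a gene presence/absence matrix
#'
#' Supports three dialects:
#' \describe{
#'   \item{`rtab`}{tab-delimited binary table, genes as rows, genomes as
#'     columns, first column the gene id, entries 0/1 (Roary/Panaroo
#'     `.Rtab`). Transposed to genomes x genes on load.}
#'   \item{`roary_csv`}{Roary `gene_presence_absence.csv`: quoted CSV with
#'     meta columns up to "Avg group size nuc" followed by one column per
#'     genome. Any non-empty genome cell (including paralog lists such as
#'     `"geneA_1;geneA_2"`) scores presence; the "Annotation" column is kept
#'     as the gene annotation.}
#'   \item{`pirate`}{PIRATE gene-families table: tab-delimited with meta
#'     columns (`allele_name`, `gene_family`, `consensus_product`,
#'     `threshold`, ..., `number_genomes`) followed by genome columns. Rows
#'     are filtered to `threshold` before loading; non-empty cell means
#'     present.}
#' }
#'
#' @param path input file.
#' @param dialect one of `"roary_csv"`, `"rtab"`, `"pirate"`.
#' @param threshold percent identity threshold used to filter PIRATE rows
#'   (default 90); ignored by the other dialects.
#' @return a [gpa_matrix()].
#' @export
read_presence_absence <- function(path, dialect = c("roary_csv", "rtab",
                                                    "pirate"),
                                  threshold = 90) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(dialect,
         rtab = read_rtab(path),
         roary_csv = read_roary_csv(path),
         pirate = read_pirate_table(path, threshold))
}

read_rtab <- function(path) {
  tab <- tryCatch(
    utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse Rtab file ", path, ": ",
                             conditionMessage(e)))
  if (ncol(tab) < 2) stop("Rtab file ", path, " has no genome columns")
  genes <- as.character(tab[[1]])
  genomes <- colnames(tab)[-1]
  if (anyDuplicated(genomes)) stop("duplicate genome column in ", path)
  vals <- as.matrix(tab[, -1, drop = FALSE])
  suppressWarnings(storage.mode(vals) <- "integer")
  bad <- which(is.na(vals) | !(vals %in% c(0L, 1L)), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("non-binary entry in ", path, " at data line ", bad[1, 1])
  }
  m <- t(vals)
  dimnames(m) <- list(genomes, genes)
  gpa_matrix(m)
}

# Fixed leading columns of Roary's gene_presence_absence.csv.
.roary_meta_cols <- c(
  "Gene", "Non-unique Gene name", "Annotation", "No. isolates",
  "No. sequences", "Avg sequences per isolate", "Genome Fragment",
  "Order within Fragment", "Accessory Fragment",
  "Accessory Order with Fragment", "QC", "Min group size nuc",
  "Max group size nuc", "Avg group size nuc")

read_roary_csv <- function(path) {
  tab <- tryCatch(
    utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character"),
    error = function(e) stop("cannot parse Roary csv ", path, ": ",
                             conditionMessage(e)))
  meta_n <- if (all(.roary_meta_cols %in% colnames(tab))) {
    max(match(.roary_meta_cols, colnames(tab)))
  } else 1L  # minimal variant: gene id column then genomes
  if (ncol(tab) <= meta_n) stop("no genome columns found in ", path)
  genomes <- colnames(tab)[(meta_n + 1):ncol(tab)]
  if (anyDuplicated(genomes)) {
    stop("duplicate genome column: ",
         genomes[duplicated(genomes)][1], " in ", path)
  }
  genes <- tab[[1]]
  cells <- as.matrix(tab[, (meta_n + 1):ncol(tab), drop = FALSE])
  m <- t(ifelse(is.na(cells) | trimws(cells) == "", 0L, 1L))
  dimnames(m) <- list(genomes, genes)
  ann <- NULL
  if ("Annotation" %in% colnames(tab)) {
    ann <- stats::setNames(tab[["Annotation"]], genes)
  }
  gpa_matrix(m, gene_annotations = ann)
}

# Meta columns expected ahead of the genome columns in PIRATE tables; the
# schema varies slightly between PIRATE outputs, so genome columns are taken
# as everything after the last recognised meta column.
.pirate_meta_cols <- c(
  "allele_name", "gene_family", "consensus_gene_name", "consensus_product",
  "threshold", "alleles_at_maximum_threshold", "number_genomes",
  "average_dose", "min_dose", "max_dose", "genomes_containing_duplications",
  "number_fission_loci", "number_duplicated_loci", "no_loci",
  "products", "gene_names", "min_length(bp)", "max_length(bp)",
  "average_length(bp)", "cluster", "cluster_order")

read_pirate_table <- function(path, threshold) {
  tab <- tryCatch(
    utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                      colClasses = "character"),
    error = function(e) stop("cannot parse PIRATE table ", path, ": ",
                             conditionMessage(e)))
  if (!"threshold" %in% colnames(tab)) {
    stop("PIRATE table ", path, " lacks a 'threshold' column")
  }
  meta_n <- max(match(intersect(.pirate_meta_cols, colnames(tab)),
                      colnames(tab)))
  if (ncol(tab) <= meta_n) stop("no genome columns found in ", path)
  keep <- as.numeric(tab$threshold) == threshold
  if (!any(keep)) {
    stop("no gene families at threshold ", threshold, " in ", path)
  }
  tab <- tab[keep, , drop = FALSE]
  id_col <- if ("gene_family" %in% colnames(tab)) "gene_family" else
    colnames(tab)[1]
  genes <- tab[[id_col]]
  if (anyDuplicated(genes)) {
    stop("duplicate gene identifier at threshold ", threshold, ": ",
         genes[duplicated(genes)][1])
  }
  genomes <- colnames(tab)[(meta_n + 1):ncol(tab)]
  if (anyDuplicated(genomes)) stop("duplicate genome column in ", path)
  cells <- as.matrix(tab[, (meta_n + 1):ncol(tab), drop = FALSE])
  m <- t(ifelse(is.na(cells) | trimws(cells) == "", 0L, 1L))
  dimnames(m) <- list(genomes, genes)
  ann <- NULL
  if ("consensus_product" %in% colnames(tab)) {
    ann <- stats::setNames(tab[["consensus_product"]], genes)
  }
  gpa_matrix(m, gene_annotations = ann, identity_threshold = threshold)
}

#' Write a presence/absence matrix as Rtab
#'
#' Genes as rows, genomes as columns, tab-delimited, 0/1 entries; the inverse
#' of `read_presence_absence(dialect = "rtab")`.
#'
#' @param m a [gpa_matrix()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_rtab <- function(m, path) {
  stopifnot(is_gpa_matrix(m))
  tab <- data.frame(Gene = gene_ids(m), t(m$values), check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genome metadata table
#'
#' Delimited text (TSV or CSV, sniffed from the header line unless given)
#' with one row per genome. Empty cells become the explicit sentinel `"NA"`
#' rather than being dropped, so downstream enrichment can opt them in or out.
#'
#' @param path input file.
#' @param id_col name of the genome-id column; by default the first of
#'   `genome`, `genome_id`, `id`, `isolate`, `name` present, else the first
#'   column.
#' @param sep field separator; `NULL` to sniff tab vs comma.
#' @return a `metadata_table`: data.frame with a `genome_id` column first and
#'   one column per categorical attribute.
#' @export
read_metadata <- function(path, id_col = NULL, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1)
    sep <- if (grepl("\t", hdr)) "\t" else ","
  }
  tab <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE, colClasses = "character",
                           quote = "\"", comment.char = "")
  if (is.null(id_col)) {
    cand <- intersect(c("genome", "genome_id", "id", "isolate", "name"),
                      colnames(tab))
    id_col <- if (length(cand)) cand[1] else colnames(tab)[1]
  }
  if (!id_col %in% colnames(tab)) {
    stop("metadata file ", path, " lacks the id column '", id_col, "'")
  }
  if (anyDuplicated(tab[[id_col]])) {
    stop("duplicated genome id in metadata: ",
         tab[[id_col]][duplicated(tab[[id_col]])][1])
  }
  attrs <- setdiff(colnames(tab), id_col)
  if (any(!nzchar(attrs))) stop("empty attribute name in ", path)
  out <- data.frame(genome_id = tab[[id_col]], tab[, attrs, drop = FALSE],
                    check.names = FALSE, stringsAsFactors = FALSE)
  for (a in attrs) {
    v <- out[[a]]
    v[is.na(v) | trimws(v) == ""] <- "NA"
    out[[a]] <- v
  }
  class(out) <- c("metadata_table", "data.frame")
  out
}

#' Construct a metadata table from a data.frame
#'
#' @param df data.frame with a `genome_id` column.
#' @return a `metadata_table`.
#' @export
as_metadata_table <- function(df) {
  stopifnot("genome_id" %in% colnames(df))
  if (anyDuplicated(df$genome_id)) stop("duplicated genome id")
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (a in setdiff(colnames(df), "genome_id")) {
    v <- as.character(df[[a]])
    v[is.na(v) | trimws(v) == ""] <- "NA"
    df[[a]] <- v
  }
  class(df) <- c("metadata_table", "data.frame")
  df
}

#' One metadata attribute as a named vector
#'
#' @param md a `metadata_table`.
#' @param attribute column name.
#' @return character vector named by genome id.
#' @export
metadata_attribute <- function(md, attribute) {
  if (!attribute %in% colnames(md)) {
    stop("unknown metadata attribute: ", attribute)
  }
  stats::setNames(md[[attribute]], md$genome_id)
}

#' Read a PIRATE-style synteny edge list
#'
#' Three whitespace/tab-delimited columns: source, target, weight. A header
#' line is auto-detected by a non-numeric third field. Self-pairs are dropped
#' with a message; weights larger than `n_genomes` (duplication artefacts)
#' are clamped with a warning.
#'
#' @param path input `.edges` file.
#' @param n_genomes optional genome count used to clamp weights.
#' @return data.frame with columns `from`, `to`, `weight`.
#' @export
read_pirate_edges <- function(path, n_genomes = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty edge file: ", path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop("edge file ", path, ": line ", which(nf < 3)[1],
         " has fewer than 3 fields")
  }
  first_w <- suppressWarnings(as.numeric(fields[[1]][3]))
  if (is.na(first_w)) fields <- fields[-1]  # header
  from <- vapply(fields, `[`, character(1), 1)
  to <- vapply(fields, `[`, character(1), 2)
  w <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 3)))
  if (anyNA(w)) {
    stop("edge file ", path, ": non-numeric weight on line ",
         which(is.na(w))[1] + (length(lines) - length(fields)))
  }
  self <- from == to
  if (any(self)) message("dropping ", sum(self), " self-pair edge(s)")
  out <- data.frame(from = from[!self], to = to[!self], weight = w[!self],
                    stringsAsFactors = FALSE)
  if (!is.null(n_genomes) && any(out$weight > n_genomes)) {
    warning(sum(out$weight > n_genomes),
            " edge weight(s) exceed the genome count; clamping to ",
            n_genomes)
    out$weight <- pmin(out$weight, n_genomes)
  }
  out
}

#' Collapse allele identifiers to gene families in an edge list
#'
#' Renames edge endpoints through an allele-to-family map, removes edges that
#' become self-loops (logged via a message) and merges parallel edges by
#' summing their weights. Total edge weight is conserved minus the removed
#' self-loop weight.
#'
#' @param edges data.frame with columns `from`, `to`, `weight`.
#' @param map named character vector: allele id -> gene family id.
#' @return data.frame with columns `from`, `to`, `weight`.
#' @export
collapse_alleles_to_families <- function(edges, map) {
  edges <- as.data.frame(edges)
  names(edges)[1:3] <- c("from", "to", "weight")
  alleles <- unique(c(edges$from, edges$to))
  missing <- setdiff(alleles, names(map))
  if (length(missing)) {
    stop("allele(s) missing from the family map: ",
         paste(utils::head(missing, 10), collapse = ", "))
  }
  from <- unname(map[edges$from])
  to <- unname(map[edges$to])
  loops <- from == to
  if (any(loops)) {
    message("removed ", sum(loops), " self-loop edge(s) (total weight ",
            sum(edges$weight[loops]), ") after collapsing alleles")
  }
  from <- from[!loops]
  to <- to[!loops]
  w <- edges$weight[!loops]
  swap <- from > to
  tmp <- from[swap]
  from[swap] <- to[swap]
  to[swap] <- tmp
  key <- paste(from, to, sep = "\r")
  agg <- tapply(w, key, sum)
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  out <- data.frame(from = vapply(parts, `[`, character(1), 1),
                    to = vapply(parts, `[`, character(1), 2),
                    weight = as.numeric(agg), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$from, out$to), , drop = FALSE]
}
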