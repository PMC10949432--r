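#' Cluster genes into operons by intergenic distance
#'
#' Genes are batched by accession and sorted by start coordinate; walking
#' the sorted list, a gene joins the current operon when the intergenic gap
#' to the preceding gene (`next_start - previous_end - 1`) is at most
#' `gap_threshold` bp and, by default, the strands agree; otherwise a new
#' operon starts.  Overlapping genes (negative gap) are treated as gap 0
#' and joined.  The result is a partition: every gene belongs to exactly
#' one operon, and operon members are consecutive in genomic order.
#'
#' @param genes data.frame with columns `gene_id`, `accession`, `start`,
#'   `end`, `strand` (1-based inclusive coordinates, strand "+" or "-").
#' @param gap_threshold maximum intergenic gap inside an operon, bp.
#' @param require_same_strand when TRUE (default) a strand switch always
#'   starts a new operon.
#' @return an `operon_map`: list with `table` (operon_id, gene_id,
#'   accession, start, end, strand) and `gene_to_operon` (named character
#'   vector).
#' @export
cluster_operons <- function(genes, gap_threshold = 500,
                            require_same_strand = TRUE) {
  genes <- validate_gene_table(genes)
  gap_threshold <- check_count(gap_threshold, "gap_threshold", 0)

  out <- list()
  for (acc in unique(genes$accession)) {
    g <- genes[genes$accession == acc, , drop = FALSE]
    g <- g[order(g$start, g$end), , drop = FALSE]
    ordinal <- 1L
    ids <- character(nrow(g))
    ids[1] <- sprintf("%s_op%04d", acc, ordinal)
    if (nrow(g) > 1) {
      for (i in 2:nrow(g)) {
        gap <- g$start[i] - g$end[i - 1] - 1L
        if (gap < 0) gap <- 0L  # overlapping genes join
        same_strand <- g$strand[i] == g$strand[i - 1]
        if (gap <= gap_threshold && (same_strand || !require_same_strand)) {
          ids[i] <- ids[i - 1]
        } else {
          ordinal <- ordinal + 1L
          ids[i] <- sprintf("%s_op%04d", acc, ordinal)
        }
      }
    }
    g$operon_id <- ids
    out[[acc]] <- g
  }
  tab <- do.call(rbind, out)
  tab <- tab[, c("operon_id", "gene_id", "accession", "start", "end",
                 "strand")]
  rownames(tab) <- NULL
  structure(list(table = tab,
                 gene_to_operon = setNames(tab$operon_id, tab$gene_id)),
            class = "operon_map")
}

#' @export
print.operon_map <- function(x, ...) {
  cat(sprintf("<operon_map> %d genes in %d operons\n",
              nrow(x$table), length(unique(x$table$operon_id))))
  invisible(x)
}

validate_gene_table <- function(genes) {
  need <- c("gene_id", "accession", "start", "end", "strand")
  if (!is.data.frame(genes) || !all(need %in% names(genes)))
    stop("gene table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!nrow(genes)) stop("gene table is empty", call. = FALSE)
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene ids in gene table", call. = FALSE)
  if (any(genes$start < 1) || any(genes$end < genes$start))
    stop("malformed coordinates (need 1 <= start <= end)", call. = FALSE)
  if (!all(genes$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'", call. = FALSE)
  genes
}

#' Read a gene table from a GFF3 file
#'
#' Parses features of the requested type and returns the flat gene table
#' used by [cluster_operons()].  A light pre-scan reports malformed rows
#' (wrong column count, missing ID attribute) with their line numbers.
#'
#' @param path GFF3 file path.
#' @param feature_type feature types to keep (default gene; CDS also
#'   common).
#' @return data.frame: gene_id, accession, start, end, strand.
#' @export
read_gene_table <- function(path, feature_type = c("gene", "CDS")) {
  lines <- readLines(path)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  rows <- list()
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9)
      stop(sprintf("GFF3 parse error at line %d: expected 9 columns, got %d",
                   i, length(f)), call. = FALSE)
    if (!f[3] %in% feature_type) next
    m <- regmatches(f[9], regexec("(?:^|;)ID=([^;]+)", f[9]))[[1]]
    if (length(m) < 2)
      stop(sprintf("GFF3 parse error at line %d: %s feature lacks ID attribute",
                   i, f[3]), call. = FALSE)
    start <- suppressWarnings(as.integer(f[4]))
    end <- suppressWarnings(as.integer(f[5]))
    if (is.na(start) || is.na(end))
      stop(sprintf("GFF3 parse error at line %d: non-numeric coordinates", i),
           call. = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = m[2], accession = f[1], start = start, end = end,
      strand = f[7], stringsAsFactors = FALSE)
  }
  if (!length(rows))
    stop("no features of type ", paste(feature_type, collapse = "/"),
         " in ", path, call. = FALSE)
  validate_gene_table(do.call(rbind, rows))
}

#' Write a gene table as GFF3
#'
#' @param genes gene table (gene_id, accession, start, end, strand).
#' @param path output path.
#' @param feature_type GFF3 type column value.
#' @return the gene table, invisibly.
#' @export
write_gene_table <- function(genes, path, feature_type = "gene") {
  genes <- validate_gene_table(genes)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("%s\timodulome\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
                     genes$accession, feature_type, genes$start, genes$end,
                     genes$strand, genes$gene_id), con)
  invisible(genes)
}

#' Write an operon map as TSV
#'
#' @param operon_map an `operon_map`.
#' @param path output path.
#' @return the map, invisibly.
#' @export
write_operon_map <- function(operon_map, path) {
  stopifnot(inherits(operon_map, "operon_map"))
  utils::write.table(operon_map$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(operon_map)
}
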