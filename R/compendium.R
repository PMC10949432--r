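#' Expression compendium container
#'
#' Bundles a genes x samples logTPM matrix with per-sample metadata, the two
#' inputs every downstream stage consumes.  Gene and sample identifiers must
#' be unique, and the metadata must cover exactly the samples present in the
#' matrix (in any order; it is re-ordered to match the matrix).
#'
#' @param values numeric matrix, genes as rows (rownames = gene ids),
#'   samples as columns (colnames = sample ids), logTPM units.
#' @param metadata data.frame with columns `sample_id`, `project`,
#'   `condition`, `replicate_index`, `is_reference`, `mapped_reads`,
#'   `fastqc_pass`.
#' @return an object of class `compendium` with elements `values` and
#'   `metadata`.
#' @export
compendium <- function(values, metadata) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry gene rownames and sample colnames",
         call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers in expression matrix", call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers in expression matrix", call. = FALSE)
  metadata <- validate_metadata(metadata)
  if (!setequal(metadata$sample_id, colnames(values)))
    stop("metadata samples and matrix columns do not match", call. = FALSE)
  metadata <- metadata[match(colnames(values), metadata$sample_id), ,
                       drop = FALSE]
  rownames(metadata) <- NULL
  structure(list(values = values, metadata = metadata),
            class = "compendium")
}

required_metadata_cols <- c("sample_id", "project", "condition",
                            "replicate_index", "is_reference",
                            "mapped_reads", "fastqc_pass")

validate_metadata <- function(metadata) {
  if (!is.data.frame(metadata))
    stop("`metadata` must be a data.frame", call. = FALSE)
  missing <- setdiff(required_metadata_cols, names(metadata))
  if (length(missing))
    stop("metadata lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(metadata$sample_id))
    stop("duplicate sample_id in metadata", call. = FALSE)
  metadata$is_reference <- as.logical(metadata$is_reference)
  metadata$fastqc_pass <- as.logical(metadata$fastqc_pass)
  metadata
}

#' @export
print.compendium <- function(x, ...) {
  cat(sprintf("<compendium> %d genes x %d samples, %d conditions, %d projects\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$metadata$condition)),
              length(unique(x$metadata$project))))
  invisible(x)
}

#' @export
dim.compendium <- function(x) dim(x$values)

#' Read an expression compendium from TSV files
#'
#' @param expression_path tab-separated matrix, first column gene ids,
#'   remaining columns one per sample.
#' @param metadata_path tab-separated sample metadata table.
#' @return a [compendium()].
#' @export
read_compendium <- function(expression_path, metadata_path) {
  expr <- utils::read.delim(expression_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  if (ncol(expr) < 2)
    stop("expression table needs a gene-id column plus >= 1 sample",
         call. = FALSE)
  values <- as.matrix(expr[, -1, drop = FALSE])
  rownames(values) <- as.character(expr[[1]])
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  compendium(values, meta)
}

#' Write an expression compendium to TSV files
#'
#' Values round-trip through [read_compendium()] to full double precision.
#'
#' @param x a [compendium()].
#' @param expression_path,metadata_path output file paths.
#' @return `x`, invisibly.
#' @export
write_compendium <- function(x, expression_path, metadata_path) {
  stopifnot(inherits(x, "compendium"))
  df <- data.frame(gene_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     expression_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$metadata, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}
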