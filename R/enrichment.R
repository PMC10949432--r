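#' iModulon and regulon recall
#'
#' Two set-overlap ratios relating a data-driven iModulon to a curated
#' regulon: iModulon recall is the shared-gene count over the iModulon
#' size, regulon recall the shared-gene count over the regulon size.
#'
#' @param imodulon_genes,regulon_genes non-empty character vectors.
#' @return named numeric vector c(imodulon_recall, regulon_recall).
#' @export
compute_recalls <- function(imodulon_genes, regulon_genes) {
  if (!length(imodulon_genes) || !length(regulon_genes))
    stop("both gene sets must be non-empty", call. = FALSE)
  imodulon_genes <- unique(imodulon_genes)
  regulon_genes <- unique(regulon_genes)
  shared <- length(intersect(imodulon_genes, regulon_genes))
  c(imodulon_recall = shared / length(imodulon_genes),
    regulon_recall = shared / length(regulon_genes))
}

#' Classify a regulatory iModulon into a recall quadrant
#'
#' With regulon recall on x and iModulon recall on y, both cut at `cut`:
#' high/high = `well_matched`, high iModulon but low regulon recall =
#' `regulon_subset` (the iModulon is a clean subset of a larger regulon),
#' low/high = `regulon_discovery` (the iModulon extends a small regulon),
#' low/low = `poorly_matched`.
#'
#' @param imodulon_recall,regulon_recall recalls in \[0, 1\].
#' @param cut quadrant boundary (default 0.6).
#' @return one of "well_matched", "regulon_subset", "regulon_discovery",
#'   "poorly_matched".
#' @export
classify_quadrant <- function(imodulon_recall, regulon_recall, cut = 0.6) {
  check_scalar(imodulon_recall, "imodulon_recall", 0, 1)
  check_scalar(regulon_recall, "regulon_recall", 0, 1)
  if (imodulon_recall >= cut) {
    if (regulon_recall >= cut) "well_matched" else "regulon_subset"
  } else {
    if (regulon_recall >= cut) "regulon_discovery" else "poorly_matched"
  }
}

#' Validate and normalize a draft TRN table
#'
#' @param trn data.frame with columns `regulator` and `gene`; duplicate
#'   pairs are dropped.
#' @return the normalized data.frame.
#' @export
validate_trn <- function(trn) {
  if (!is.data.frame(trn) || !all(c("regulator", "gene") %in% names(trn)))
    stop("TRN table needs `regulator` and `gene` columns", call. = FALSE)
  trn <- unique(trn[, c("regulator", "gene")])
  if (any(trn$gene == "" | is.na(trn$gene)))
    stop("TRN table contains empty gene identifiers", call. = FALSE)
  rownames(trn) <- NULL
  trn
}

#' Enrich iModulons against a draft TRN
#'
#' One-sided Fisher exact (hypergeometric upper-tail) test of the overlap
#' between every (iModulon, regulator) pair against the gene universe of
#' the expression matrix, Benjamini-Hochberg correction across the full
#' pair grid, recall metrics, and quadrant classification.  The best
#' (lowest-q) regulator with q <= alpha is attached to each iModulon,
#' upgrading its category to `regulatory`.
#'
#' @param imodulons an `imodulon_set` from [extract_imodulons()].
#' @param trn draft TRN table (regulator, gene).
#' @param background character vector: the gene universe (all genes the
#'   decomposition saw).  Must cover all iModulon genes.
#' @param alpha FDR level for attaching a regulator.
#' @param quadrant_cut passed to [classify_quadrant()].
#' @return a list with `table` (one row per tested pair: imodulon,
#'   regulator, overlap, imodulon_size, regulon_size, p_value, q_value,
#'   imodulon_recall, regulon_recall, quadrant) and `imodulons` (the input
#'   set with enrichment attached).
#' @export
enrich_regulons <- function(imodulons, trn, background, alpha = 0.05,
                            quadrant_cut = 0.6) {
  stopifnot(inherits(imodulons, "imodulon_set"))
  trn <- validate_trn(trn)
  background <- unique(background)
  n_bg <- length(background)
  regulons <- split(trn$gene, trn$regulator)
  regulons <- lapply(regulons, function(g) {
    g <- intersect(unique(g), background)
    g
  })
  empty <- vapply(regulons, length, 1L) == 0
  if (any(empty)) {
    warning("regulator(s) with no genes in background skipped: ",
            paste(names(regulons)[empty], collapse = ", "), call. = FALSE)
    regulons <- regulons[!empty]
  }

  rows <- list()
  for (im in imodulons$imodulons) {
    genes <- intersect(im$member_genes, background)
    if (!length(genes)) next
    for (reg in names(regulons)) {
      rg <- regulons[[reg]]
      ov <- length(intersect(genes, rg))
      # hypergeometric upper tail: P(overlap >= ov)
      p <- stats::phyper(ov - 1, length(rg), n_bg - length(rg),
                         length(genes), lower.tail = FALSE)
      rec <- compute_recalls(genes, rg)
      rows[[length(rows) + 1L]] <- data.frame(
        imodulon = im$name, regulator = reg, overlap = ov,
        imodulon_size = length(genes), regulon_size = length(rg),
        p_value = p, q_value = NA_real_,
        imodulon_recall = rec[["imodulon_recall"]],
        regulon_recall = rec[["regulon_recall"]],
        quadrant = classify_quadrant(rec[["imodulon_recall"]],
                                     rec[["regulon_recall"]],
                                     cut = quadrant_cut),
        stringsAsFactors = FALSE)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(imodulon = character(), regulator = character(),
               overlap = integer(), imodulon_size = integer(),
               regulon_size = integer(), p_value = numeric(),
               q_value = numeric(), imodulon_recall = numeric(),
               regulon_recall = numeric(), quadrant = character(),
               stringsAsFactors = FALSE)
  tab$q_value <- stats::p.adjust(tab$p_value, method = "BH")

  for (nm in names(imodulons$imodulons)) {
    sub <- tab[tab$imodulon == nm & tab$q_value <= alpha, , drop = FALSE]
    if (!nrow(sub)) next
    best <- sub[order(sub$q_value, sub$p_value, -sub$overlap), ][1, ]
    imodulons$imodulons[[nm]]$enrichment <- best
    if (imodulons$imodulons[[nm]]$category != "single-gene") {
      imodulons$imodulons[[nm]]$category <- "regulatory"
      imodulons$summary$category[imodulons$summary$name == nm] <- "regulatory"
    }
  }
  list(table = tab, imodulons = imodulons)
}

#' Read / write a TRN table as TSV
#'
#' @param path file path; tab-separated with columns regulator, gene.
#' @return [read_trn()]: the validated data.frame.
#' @export
read_trn <- function(path) {
  validate_trn(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_trn
#' @param trn TRN data.frame to write.
#' @export
write_trn <- function(trn, path) {
  utils::write.table(validate_trn(trn), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(trn)
}
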