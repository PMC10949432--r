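#' Write an iModulon set as JSON and TSV
#'
#' @param imodulons an `imodulon_set`.
#' @param json_path,tsv_path output paths (either may be NULL).
#' @return the set, invisibly.
#' @export
write_imodulons <- function(imodulons, json_path = NULL, tsv_path = NULL) {
  stopifnot(inherits(imodulons, "imodulon_set"))
  if (!is.null(json_path)) {
    obj <- lapply(imodulons$imodulons, function(m) {
      list(name = m$name,
           component_index = m$component_index,
           genes = as.list(m$member_genes),
           threshold = m$threshold,
           explained_variance = m$explained_variance,
           category = m$category,
           regulator = if (!is.null(m$enrichment)) m$enrichment$regulator
                       else NA)
    })
    jsonlite::write_json(unname(obj), json_path, auto_unbox = TRUE,
                         digits = NA)
  }
  if (!is.null(tsv_path)) {
    tab <- imodulons$summary
    tab$regulator <- vapply(imodulons$imodulons, function(m)
      if (!is.null(m$enrichment)) m$enrichment$regulator else NA_character_,
      "")
    tab$genes <- vapply(imodulons$imodulons, function(m)
      paste(m$member_genes, collapse = ","), "")
    utils::write.table(tab, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(imodulons)
}

#' Load and validate a pipeline configuration
#'
#' Accepts a YAML/JSON file path or a list; fills defaults for every tuning
#' knob and checks that all referenced input paths exist.  A master `seed`
#' is mandatory; per-stage seeds are derived from it with [derive_seed()].
#'
#' @param config list or path to a YAML/JSON configuration file.
#' @return validated config list (class `pipeline_config`).
#' @export
load_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or file", call. = FALSE)
  if (is.null(config$seed)) stop("config must set `seed`", call. = FALSE)

  defaults <- list(
    qc = list(min_reads = 5e5, correlation_threshold = 0.80,
              sweep = c(0.80, 0.85, 0.90, 0.95)),
    ica = list(dimension = NULL, sweep = NULL, restarts = 10),
    thresholding = list(method = "dagostino", p_cutoff = 1e-4),
    enrichment = list(alpha = 0.05, quadrant_cut = 0.6),
    operons = list(gap_threshold = 500, require_same_strand = TRUE),
    pssm = list(pseudocount = 0.5, background = "promoters"),
    classifier = list(l1_ratio = 0.5, k_neighbors = 5, folds = 5,
                      regulator = NULL),
    outdir = "imodulome_output"
  )
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
    else if (is.list(defaults[[nm]]))
      for (k in names(defaults[[nm]]))
        if (is.null(config[[nm]][[k]])) config[[nm]][[k]] <- defaults[[nm]][[k]]
  }
  if (is.null(config$paths$expression) || is.null(config$paths$metadata))
    stop("config$paths must provide `expression` and `metadata`",
         call. = FALSE)
  for (p in unlist(config$paths))
    if (!file.exists(p)) stop("input path does not exist: ", p,
                              call. = FALSE)
  class(config) <- c("pipeline_config", class(config))
  config
}

#' Run the full iModulon reconstruction pipeline
#'
#' Executes QC (exclusion, replicate-correlation filtering, reference
#' centering), robust ICA (fixed dimension or sweep + automatic
#' selection), iModulon extraction, and -- when the corresponding inputs
#' are configured -- regulon enrichment, operon clustering, promoter motif
#' scoring, and the regulon-membership classifier.  Failure of an optional
#' stage (enrichment, operons, motifs, classifier) is logged and does not
#' abort the core ICA path.  Every artifact is written under
#' `config$outdir` together with a manifest recording the seed, the
#' configuration, and a checksum per output file.
#'
#' @param config see [load_pipeline_config()].
#' @return invisible list of stage results (`qc`, `ica`, `imodulons`,
#'   `enrichment`, `operons`, `motifs`, `classifier`, `manifest`).
#' @export
run_pipeline <- function(config) {
  config <- load_pipeline_config(config)
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  log_msg <- function(...) message(sprintf("[imodulome] %s", sprintf(...)))
  results <- list()

  # ---- QC ------------------------------------------------------------
  x <- read_compendium(config$paths$expression, config$paths$metadata)
  log_msg("loaded %d genes x %d samples", nrow(x$values), ncol(x$values))
  qc1 <- exclude_failing_samples(x, min_reads = config$qc$min_reads)
  qc2 <- replicate_correlation_filter(qc1$compendium,
                                      threshold = config$qc$correlation_threshold)
  sweep_tab <- qc_threshold_sweep(qc1$compendium, config$qc$sweep)
  xc <- center_to_reference(qc2$compendium)
  write_compendium(xc, file.path(outdir, "expression_filtered.tsv"),
                   file.path(outdir, "metadata_filtered.tsv"))
  qc_report <- list(
    excluded_samples = qc1$report$excluded_samples,
    averaged_groups = qc2$report$averaged_groups,
    threshold_used = config$qc$correlation_threshold,
    threshold_sweep = sweep_tab)
  jsonlite::write_json(qc_report, file.path(outdir, "qc_report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  results$qc <- qc_report
  log_msg("QC: %d excluded, %d groups averaged",
          nrow(qc1$report$excluded_samples),
          length(qc2$report$averaged_groups))

  # ---- ICA -----------------------------------------------------------
  dimension <- config$ica$dimension
  if (!is.null(config$ica$sweep)) {
    sweep_stats <- sweep_dimensions(xc, config$ica$sweep,
                                    n_restarts = config$ica$restarts,
                                    seed = derive_seed(seed, "sweep"))
    utils::write.table(sweep_stats, file.path(outdir, "dimension_sweep.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    dimension <- as.integer(select_optimal_dimension(sweep_stats))
    log_msg("dimension sweep selected d = %d", dimension)
  }
  if (is.null(dimension))
    stop("config$ica must set `dimension` or `sweep`", call. = FALSE)
  dec <- run_ica(xc, dimension = dimension,
                 n_restarts = config$ica$restarts,
                 seed = derive_seed(seed, "ica"))
  write_ica_matrices(dec, file.path(outdir, "M.tsv"),
                     file.path(outdir, "A.tsv"))
  results$ica <- dec
  log_msg("ICA: %d robust components at dimension %d", ncol(dec$M),
          dimension)

  # ---- iModulons ------------------------------------------------------
  ims <- extract_imodulons(xc, dec, method = config$thresholding$method,
                           p_cutoff = config$thresholding$p_cutoff)
  if (nrow(dec$A) >= 2) {
    cl <- correlate_and_cluster_imodulons(dec$A)
    utils::write.table(
      data.frame(component = names(cl$clusters), cluster = cl$clusters),
      file.path(outdir, "activity_clusters.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(hclust_to_newick(cl$hclust),
               file.path(outdir, "activity_dendrogram.nwk"))
  }

  # ---- enrichment (optional) -----------------------------------------
  results$enrichment <- run_optional("enrichment", log_msg, {
    if (is.null(config$paths$trn)) stop("no TRN path configured")
    trn <- read_trn(config$paths$trn)
    en <- enrich_regulons(ims, trn, background = rownames(xc$values),
                          alpha = config$enrichment$alpha,
                          quadrant_cut = config$enrichment$quadrant_cut)
    ims <- en$imodulons
    utils::write.table(en$table, file.path(outdir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    scatter <- en$table[, c("imodulon", "regulator", "regulon_recall",
                            "imodulon_recall", "overlap", "quadrant")]
    utils::write.table(scatter, file.path(outdir, "recall_scatter.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    en$table
  })
  write_imodulons(ims, file.path(outdir, "imodulons.json"),
                  file.path(outdir, "imodulons.tsv"))
  results$imodulons <- ims

  # ---- operons / motifs / classifier (optional) ----------------------
  operon_map <- NULL
  results$operons <- run_optional("operons", log_msg, {
    if (is.null(config$paths$gff3)) stop("no GFF3 path configured")
    genes <- read_gene_table(config$paths$gff3)
    operon_map <- cluster_operons(
      genes, gap_threshold = config$operons$gap_threshold,
      require_same_strand = config$operons$require_same_strand)
    write_operon_map(operon_map, file.path(outdir, "operons.tsv"))
    operon_map
  })

  scores <- NULL
  results$motifs <- run_optional("motifs", log_msg, {
    if (is.null(operon_map)) stop("operon stage did not run")
    if (is.null(config$paths$promoters) || is.null(config$paths$sites))
      stop("promoter/site paths not configured")
    sites <- read_sites(config$paths$sites)
    promoters <- read_promoters(config$paths$promoters)
    bg <- switch(config$pssm$background,
                 promoters = paste(promoters, collapse = ""),
                 sites = paste(sites, collapse = ""),
                 config$pssm$background)
    pssm <- build_pssm(sites, bg, pseudocount = config$pssm$pseudocount)
    write_pssm_json(pssm, file.path(outdir, "pssm.json"))
    scores <- score_operon_promoters(operon_map, promoters, pssm)
    utils::write.table(scores, file.path(outdir, "motif_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    scores
  })

  results$classifier <- run_optional("classifier", log_msg, {
    if (is.null(scores)) stop("motif stage did not run")
    if (is.null(config$paths$trn) || is.null(config$classifier$regulator))
      stop("classifier needs a TRN and config$classifier$regulator")
    trn <- read_trn(config$paths$trn)
    regulon <- trn$gene[trn$regulator == config$classifier$regulator]
    gm <- gene_motif_scores(scores, operon_map)
    feats <- matrix(gm$best_score, ncol = 1,
                    dimnames = list(gm$gene_id, "best_score"))
    labels <- setNames(as.integer(gm$gene_id %in% regulon), gm$gene_id)
    report <- evaluate_cv(feats, labels, operon_map,
                          k = config$classifier$folds,
                          l1_ratio = config$classifier$l1_ratio,
                          k_neighbors = config$classifier$k_neighbors,
                          seed = derive_seed(seed, "classifier"))
    jsonlite::write_json(
      list(fold_aucs = report$fold_aucs, mean_auc = report$mean_auc,
           passed_benchmark = report$passed_benchmark,
           coefficients = as.list(report$coefficients),
           lambda = report$lambda, seed = report$seed),
      file.path(outdir, "classifier_report.json"),
      auto_unbox = TRUE, digits = NA)
    report
  })

  # ---- manifest ------------------------------------------------------
  cfg_file <- file.path(outdir, "config_used.json")
  jsonlite::write_json(unclass(config), cfg_file, auto_unbox = TRUE,
                       digits = NA, null = "null")
  outputs <- setdiff(list.files(outdir), "manifest.json")
  checksums <- as.list(tools::md5sum(file.path(outdir, outputs)))
  names(checksums) <- outputs
  manifest <- list(package_version = as.character(
                     utils::packageVersion("imodulome")),
                   seed = seed,
                   config_md5 = unname(tools::md5sum(cfg_file)),
                   outputs = checksums)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  results$manifest <- manifest
  log_msg("pipeline complete; outputs in %s", outdir)
  invisible(results)
}

# Run an optional stage, logging failure instead of aborting.
run_optional <- function(stage, log_msg, expr) {
  tryCatch(expr, error = function(e) {
    log_msg("stage '%s' skipped: %s", stage, conditionMessage(e))
    NULL
  })
}

# Serialize an hclust object to Newick text (branch lengths from merge
# heights).
hclust_to_newick <- function(hc) {
  build <- function(node, parent_height) {
    if (node < 0) {
      sprintf("%s:%.6f", hc$labels[-node], parent_height)
    } else {
      h <- hc$height[node]
      left <- build(hc$merge[node, 1], h)
      right <- build(hc$merge[node, 2], h)
      sprintf("(%s,%s):%.6f", left, right, max(parent_height - h, 0))
    }
  }
  n <- length(hc$height)
  paste0(sub(":[0-9.]+$", "", build(n, hc$height[n])), ";")
}
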