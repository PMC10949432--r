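#' Generate a synthetic expression compendium with planted modules
#'
#' Emulates the structure of a bacterial RNA-seq compendium (logTPM, a
#' moderate number of conditions sampled with biological replicates, grouped
#' into projects that stand in for media types) while planting a known
#' low-rank regulatory structure: `X = M A + E`, where `M` holds `k_modules`
#' sparse gene-weight columns and `A` holds per-sample module activities.
#' Condition-level activities are shared by replicates; replicate-level
#' jitter is solved analytically so the expected within-condition Pearson
#' correlation between replicate columns is approximately `replicate_rho`.
#'
#' Writing `s2 = sum(M^2)/n_genes` for the signal variance per gene, the
#' jitter standard deviation `tau` satisfies
#' `tau^2 = max(0, 1/rho - 1 - noise_sd^2/s2)`; at `noise_sd = 0`,
#' `replicate_rho = 1` replicate columns are identical.
#'
#' @param n_genes number of genes.
#' @param n_conditions number of biological conditions.
#' @param replicates_per_condition replicates per condition (>= 2).
#' @param k_modules number of planted modules (< min(genes, samples)).
#' @param noise_sd additive Gaussian noise sd, logTPM units.
#' @param replicate_rho target within-condition replicate correlation, in
#'   (0, 1].
#' @param seed integer seed; the same seed reproduces the output bit for bit.
#' @param module_size genes per module; default `max(4, n_genes %/% (2 * k))`
#'   keeps modules disjoint and non-degenerate.
#' @param conditions_per_project conditions chunked into each project
#'   (emulating media types); the first condition of each project is the
#'   project's reference condition.
#' @param mapped_reads mapped-read count stamped on every sample.
#' @return a list with elements `compendium` (a [compendium()]) and `truth`
#'   (class `ground_truth`: planted `module_weights`, `module_activities`,
#'   `regulon_labels`, `noise_sd`, `replicate_rho`, `seed`).
#' @export
generate_compendium <- function(n_genes, n_conditions,
                                replicates_per_condition, k_modules,
                                noise_sd, replicate_rho, seed,
                                module_size = NULL,
                                conditions_per_project = 4,
                                mapped_reads = 2e6) {
  n_genes <- check_count(n_genes, "n_genes", 2)
  n_conditions <- check_count(n_conditions, "n_conditions", 1)
  replicates_per_condition <- check_count(replicates_per_condition,
                                          "replicates_per_condition", 2)
  k_modules <- check_count(k_modules, "k_modules", 1)
  check_scalar(noise_sd, "noise_sd", lower = 0)
  check_scalar(replicate_rho, "replicate_rho", lower = 0, upper = 1,
               open_lower = TRUE)
  n_samples <- n_conditions * replicates_per_condition
  if (k_modules >= min(n_genes, n_samples))
    stop("k_modules must be < min(n_genes, n_conditions * replicates)",
         call. = FALSE)
  if (is.null(module_size))
    module_size <- max(4L, n_genes %/% (2L * k_modules))
  module_size <- check_count(module_size, "module_size", 2)
  if (module_size * k_modules > n_genes)
    stop("module_size * k_modules exceeds n_genes", call. = FALSE)

  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  cond_ids <- sprintf("cond%02d", seq_len(n_conditions))

  with_seed(seed, {
    # Sparse gene-weight matrix: disjoint member sets, signed weights well
    # above the noise floor.
    member_pool <- sample(n_genes, module_size * k_modules)
    M <- matrix(0, n_genes, k_modules,
                dimnames = list(gene_ids, sprintf("mod%02d", seq_len(k_modules))))
    regulons <- list()
    for (k in seq_len(k_modules)) {
      idx <- member_pool[((k - 1) * module_size + 1):(k * module_size)]
      M[idx, k] <- runif(module_size, 1, 2) * sample(c(-1, 1), module_size,
                                                     replace = TRUE)
      regulons[[sprintf("Reg%02d", k)]] <- gene_ids[idx]
    }

    # Condition-level activities, replicate jitter solved from the target
    # within-condition correlation.
    Z <- matrix(rnorm(k_modules * n_conditions), k_modules, n_conditions)
    s2 <- sum(M^2) / n_genes
    tau2 <- max(0, 1 / replicate_rho - 1 - noise_sd^2 / s2)
    sample_ids <- as.vector(t(outer(cond_ids, seq_len(replicates_per_condition),
                                    function(c, r) paste0(c, "_r", r))))
    A <- Z[, rep(seq_len(n_conditions), each = replicates_per_condition),
           drop = FALSE] +
      sqrt(tau2) * matrix(rnorm(k_modules * n_samples), k_modules, n_samples)
    dimnames(A) <- list(colnames(M), sample_ids)

    X <- M %*% A
    if (noise_sd > 0)
      X <- X + matrix(rnorm(length(X), sd = noise_sd), nrow(X), ncol(X))
    dimnames(X) <- list(gene_ids, sample_ids)

    n_projects <- ceiling(n_conditions / conditions_per_project)
    project_of_cond <- rep(sprintf("proj%02d", seq_len(n_projects)),
                           each = conditions_per_project)[seq_len(n_conditions)]
    reference_cond <- tapply(cond_ids, project_of_cond, `[`, 1)
    cond_of_sample <- rep(cond_ids, each = replicates_per_condition)
    proj_of_sample <- project_of_cond[match(cond_of_sample, cond_ids)]
    metadata <- data.frame(
      sample_id = sample_ids,
      project = proj_of_sample,
      condition = cond_of_sample,
      replicate_index = rep(seq_len(replicates_per_condition), n_conditions),
      is_reference = cond_of_sample %in% reference_cond[proj_of_sample],
      mapped_reads = mapped_reads,
      fastqc_pass = TRUE,
      stringsAsFactors = FALSE
    )

    truth <- structure(list(
      module_weights = M,
      module_activities = A,
      condition_activities = Z,
      noise_sd = noise_sd,
      replicate_rho = replicate_rho,
      replicate_jitter_sd = sqrt(tau2),
      regulon_labels = regulons,
      seed = as.integer(seed)
    ), class = "ground_truth")

    list(compendium = compendium(X, metadata), truth = truth)
  })
}

#' Generate a synthetic genome layout with known operon structure
#'
#' Lays `n_genes` genes on one or more accessions so that consecutive genes
#' inside a truth operon are separated by exactly `gap_within` bp and operon
#' boundaries by `gap_between` bp.  Each operon's lead gene receives a
#' fixed-length upstream promoter sequence drawn from a uniform ACGT
#' background; a configurable subset of promoters gets one binding-site
#' instance sampled from `motif_pwm` planted at a recorded offset.
#'
#' @param n_genes total gene count.
#' @param n_operons number of operons (<= n_genes); sizes as even as
#'   possible.
#' @param gap_within intergenic gap inside an operon, bp (>= 0).
#' @param gap_between gap between operons, bp (> gap_within).
#' @param seed integer seed.
#' @param gene_length length of every gene body, bp.
#' @param promoter_length upstream region emitted per operon, bp.
#' @param motif_pwm optional position probability matrix (4 x width, rows
#'   A,C,G,T) used to plant one site per selected promoter.
#' @param motif_operons operon indices receiving a planted site; default all
#'   when `motif_pwm` is given.
#' @param motif_mode `"sample"` draws each planted site from the PWM
#'   (realistic, sites carry errors); `"consensus"` plants the most
#'   probable base at every position (guarantees the planted window is the
#'   unique top scorer at its recorded offset).
#' @param n_accessions number of accessions the operons are spread across.
#' @return a list with `genes` (data.frame: gene_id, accession, start, end,
#'   strand), `promoters` (named character vector, one per operon, keyed by
#'   the operon's lead gene id), `operon_truth` (data.frame: operon_id,
#'   gene_id), and `planted_sites` (data.frame: operon_id, lead_gene,
#'   offset 0-based, site).
#' @export
generate_genome <- function(n_genes, n_operons, gap_within = 50,
                            gap_between = 600, seed = 1,
                            gene_length = 900, promoter_length = 300,
                            motif_pwm = NULL, motif_operons = NULL,
                            motif_mode = c("sample", "consensus"),
                            n_accessions = 1) {
  motif_mode <- match.arg(motif_mode)
  n_genes <- check_count(n_genes, "n_genes", 1)
  n_operons <- check_count(n_operons, "n_operons", 1)
  gap_within <- check_count(gap_within, "gap_within", 0)
  gap_between <- check_count(gap_between, "gap_between", 0)
  if (n_operons > n_genes)
    stop("n_operons must be <= n_genes", call. = FALSE)
  if (gap_within >= gap_between)
    stop("gap_within must be < gap_between", call. = FALSE)
  if (!is.null(motif_pwm)) {
    check_pwm(motif_pwm)
    if (is.null(motif_operons)) motif_operons <- seq_len(n_operons)
  }

  sizes <- rep(n_genes %/% n_operons, n_operons)
  extra <- n_genes %% n_operons
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  # contiguous blocks of operons per accession
  acc_of_operon <- sort(rep(seq_len(n_accessions), length.out = n_operons))

  with_seed(seed, {
    gene_ids <- sprintf("g%04d", seq_len(n_genes))
    rows <- vector("list", n_genes)
    truth <- vector("list", n_operons)
    operon_ids <- sprintf("operon_%03d", seq_len(n_operons))
    promoters <- character(n_operons)
    lead_genes <- character(n_operons)
    planted <- list()
    gi <- 1L
    cursor <- promoter_length + 1L
    last_acc <- acc_of_operon[1]
    for (o in seq_len(n_operons)) {
      acc <- sprintf("ACC%02d", acc_of_operon[o])
      if (acc_of_operon[o] != last_acc) {
        cursor <- promoter_length + 1L  # new accession restarts coordinates
        last_acc <- acc_of_operon[o]
      }
      lead_genes[o] <- gene_ids[gi]
      for (j in seq_len(sizes[o])) {
        start <- cursor
        end <- cursor + gene_length - 1L
        rows[[gi]] <- data.frame(gene_id = gene_ids[gi], accession = acc,
                                 start = start, end = end, strand = "+",
                                 stringsAsFactors = FALSE)
        truth[[o]] <- c(truth[[o]], gene_ids[gi])
        cursor <- end + 1L +
          if (j < sizes[o]) gap_within else gap_between
        gi <- gi + 1L
      }
      seqc <- sample(c("A", "C", "G", "T"), promoter_length, replace = TRUE)
      if (!is.null(motif_pwm) && o %in% motif_operons) {
        w <- ncol(motif_pwm)
        site <- if (motif_mode == "consensus") {
          paste(rownames(motif_pwm)[apply(motif_pwm, 2, which.max)],
                collapse = "")
        } else sample_site(motif_pwm)
        off <- sample.int(promoter_length - w + 1L, 1L) - 1L  # 0-based
        seqc[(off + 1):(off + w)] <- strsplit(site, "")[[1]]
        planted[[length(planted) + 1L]] <-
          data.frame(operon_id = operon_ids[o], lead_gene = lead_genes[o],
                     offset = off, site = site, stringsAsFactors = FALSE)
      }
      promoters[o] <- paste(seqc, collapse = "")
    }
    names(promoters) <- lead_genes
    genes <- do.call(rbind, rows)
    operon_truth <- data.frame(
      operon_id = rep(operon_ids, times = sizes),
      gene_id = unlist(truth),
      stringsAsFactors = FALSE
    )
    planted_sites <- if (length(planted)) do.call(rbind, planted) else
      data.frame(operon_id = character(), lead_gene = character(),
                 offset = integer(), site = character(),
                 stringsAsFactors = FALSE)
    list(genes = genes, promoters = promoters,
         operon_truth = operon_truth, planted_sites = planted_sites)
  })
}

# Draw one site (character string) from a position probability matrix.
sample_site <- function(pwm) {
  bases <- rownames(pwm)
  paste(vapply(seq_len(ncol(pwm)),
               function(j) sample(bases, 1, prob = pwm[, j]), ""),
        collapse = "")
}

check_pwm <- function(pwm) {
  if (!is.matrix(pwm) || nrow(pwm) != 4 ||
      !identical(rownames(pwm), c("A", "C", "G", "T")))
    stop("motif PWM must be a 4 x width matrix with rows A,C,G,T",
         call. = FALSE)
  if (any(abs(colSums(pwm) - 1) > 1e-6))
    stop("motif PWM columns must sum to 1", call. = FALSE)
  invisible(pwm)
}

#' Generate a draft regulator-to-gene table from planted ground truth
#'
#' For each planted module, emits a regulon containing a controlled fraction
#' of its genes plus a configurable number of random non-member genes, so
#' downstream recall values are known by construction.
#'
#' @param truth the `ground_truth` from [generate_compendium()].
#' @param overlap_fraction fraction of each module's genes included in its
#'   regulon, in \[0, 1\] (rounded to the nearest gene count).
#' @param extra_genes random non-member genes added per regulon.
#' @param seed integer seed.
#' @return data.frame with columns `regulator` and `gene`.
#' @export
generate_trn_table <- function(truth, overlap_fraction, extra_genes = 0,
                               seed = 1) {
  stopifnot(inherits(truth, "ground_truth"))
  check_scalar(overlap_fraction, "overlap_fraction", 0, 1)
  extra_genes <- check_count(extra_genes, "extra_genes", 0)
  if (!length(truth$regulon_labels))
    stop("ground truth has no planted modules", call. = FALSE)
  all_genes <- rownames(truth$module_weights)
  with_seed(seed, {
    rows <- lapply(names(truth$regulon_labels), function(reg) {
      members <- truth$regulon_labels[[reg]]
      n_keep <- round(overlap_fraction * length(members))
      keep <- if (n_keep > 0) sample(members, n_keep) else character()
      pool <- setdiff(all_genes, members)
      extras <- if (extra_genes > 0)
        sample(pool, min(extra_genes, length(pool))) else character()
      genes <- c(keep, extras)
      if (!length(genes)) return(NULL)
      data.frame(regulator = reg, gene = genes, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
      out <- data.frame(regulator = character(), gene = character(),
                        stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  })
}
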