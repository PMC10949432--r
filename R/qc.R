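#' Exclude samples failing basic quality rules
#'
#' Drops samples that (a) have fewer than `min_reads` reads mapped to coding
#' sequences, (b) fail the upstream FASTQC screen, (c) lack usable metadata
#' (missing project or condition), and finally (d) are left without any
#' replicate partner in their (project, condition) group once the other
#' rules have been applied.
#'
#' @param x a [compendium()].
#' @param min_reads minimum mapped-read count to retain a sample.
#' @return a list with `compendium` (filtered) and `report` (a `qc_report`:
#'   data.frame of excluded samples with reason codes in
#'   `low_reads`, `fastqc_fail`, `no_metadata`, `no_replicate`).
#' @export
exclude_failing_samples <- function(x, min_reads = 500000) {
  stopifnot(inherits(x, "compendium"))
  check_scalar(min_reads, "min_reads", lower = 0)
  md <- x$metadata
  reason <- rep(NA_character_, nrow(md))
  no_meta <- is.na(md$project) | is.na(md$condition) |
    md$project == "" | md$condition == ""
  reason[no_meta] <- "no_metadata"
  reason[is.na(reason) & (is.na(md$fastqc_pass) | !md$fastqc_pass)] <-
    "fastqc_fail"
  reason[is.na(reason) & md$mapped_reads < min_reads] <- "low_reads"

  keep <- is.na(reason)
  grp <- paste(md$project, md$condition, sep = "\r")
  sizes <- table(grp[keep])
  lone <- keep & grp %in% names(sizes)[sizes < 2]
  reason[lone] <- "no_replicate"
  keep <- is.na(reason)
  if (!any(keep))
    stop("no samples survive quality filtering", call. = FALSE)

  excluded <- data.frame(sample_id = md$sample_id[!keep],
                         reason = reason[!keep],
                         stringsAsFactors = FALSE)
  out <- compendium(x$values[, keep, drop = FALSE],
                    md[keep, , drop = FALSE])
  report <- structure(list(excluded_samples = excluded,
                           averaged_groups = list(),
                           threshold_used = NA_real_),
                      class = "qc_report")
  list(compendium = out, report = report)
}

#' Replicate-correlation filtering and averaging
#'
#' For every (project, condition) replicate group, computes all pairwise
#' Pearson correlations between the member expression profiles.  A group in
#' which any pair falls below `threshold` is judged internally inconsistent
#' and replaced by a single representative column equal to the unweighted
#' arithmetic mean of its members (sample id `<condition>_avg`); consistent
#' groups pass through unchanged.
#'
#' @param x a [compendium()]; every (project, condition) group must hold at
#'   least two samples.
#' @param threshold minimum acceptable pairwise Pearson r (default 0.80).
#' @return a list with `compendium` and `report` (`qc_report` whose
#'   `averaged_groups` records, per collapsed group, the condition, member
#'   sample ids, and the pairwise r values).
#' @export
replicate_correlation_filter <- function(x, threshold = 0.80) {
  stopifnot(inherits(x, "compendium"))
  check_scalar(threshold, "threshold", lower = -1, upper = 1)
  md <- x$metadata
  grp <- paste(md$project, md$condition, sep = "\r")
  groups <- split(seq_len(nrow(md)), grp)
  small <- vapply(groups, length, 1L) < 2
  if (any(small))
    stop("replicate groups with < 2 samples: ",
         paste(unique(md$condition[unlist(groups[small])]), collapse = ", "),
         call. = FALSE)

  sds <- apply(x$values, 2, sd)
  if (any(sds == 0))
    stop("zero-variance sample(s), Pearson r undefined: ",
         paste(colnames(x$values)[sds == 0], collapse = ", "),
         call. = FALSE)

  keep_cols <- list()
  new_meta <- list()
  averaged <- list()
  # preserve original column order; iterate groups by first appearance
  ord <- order(vapply(groups, min, 1L))
  for (g in groups[ord]) {
    cols <- x$values[, g, drop = FALSE]
    r <- cor(cols)
    pair_r <- r[upper.tri(r)]
    if (length(pair_r) && any(pair_r < threshold)) {
      avg <- rowMeans(cols)
      cond <- md$condition[g[1]]
      id <- paste0(cond, "_avg")
      m <- md[g[1], , drop = FALSE]
      m$sample_id <- id
      m$replicate_index <- 1L
      m$mapped_reads <- sum(md$mapped_reads[g])
      keep_cols[[length(keep_cols) + 1L]] <-
        matrix(avg, ncol = 1, dimnames = list(rownames(x$values), id))
      new_meta[[length(new_meta) + 1L]] <- m
      averaged[[length(averaged) + 1L]] <-
        list(condition = cond, members = md$sample_id[g],
             pairwise_r = as.numeric(pair_r))
    } else {
      keep_cols[[length(keep_cols) + 1L]] <- cols
      new_meta[[length(new_meta) + 1L]] <- md[g, , drop = FALSE]
    }
  }
  values <- do.call(cbind, keep_cols)
  meta <- do.call(rbind, new_meta)
  report <- structure(list(excluded_samples =
                             data.frame(sample_id = character(),
                                        reason = character(),
                                        stringsAsFactors = FALSE),
                           averaged_groups = averaged,
                           threshold_used = threshold),
                      class = "qc_report")
  list(compendium = compendium(values, meta), report = report)
}

#' Sweep the replicate-correlation threshold
#'
#' Re-runs [replicate_correlation_filter()] at each threshold and counts the
#' collapsed groups, mirroring the stringency comparison customarily done at
#' 0.80, 0.85, 0.90 and 0.95 before fixing the working threshold.
#'
#' @param x a [compendium()].
#' @param thresholds numeric vector of thresholds.
#' @return data.frame with columns `threshold` and `n_averaged_groups`.
#' @export
qc_threshold_sweep <- function(x, thresholds = c(0.80, 0.85, 0.90, 0.95)) {
  n <- vapply(thresholds, function(th)
    length(replicate_correlation_filter(x, th)$report$averaged_groups), 1L)
  data.frame(threshold = thresholds, n_averaged_groups = n)
}

#' Center each project on its reference condition
#'
#' Subtracts, gene-wise, the mean expression profile of a project's
#' reference-condition samples from every sample in that project, so each
#' project's reference group averages to exactly zero.  Centering an
#' already-centered compendium is a no-op.
#'
#' @param x a [compendium()]; every project must contain at least one sample
#'   flagged `is_reference`.
#' @return the centered [compendium()].
#' @export
center_to_reference <- function(x) {
  stopifnot(inherits(x, "compendium"))
  md <- x$metadata
  values <- x$values
  for (p in unique(md$project)) {
    in_p <- md$project == p
    ref <- in_p & md$is_reference
    if (!any(ref))
      stop(sprintf("project '%s' has no reference-condition sample", p),
           call. = FALSE)
    ref_mean <- rowMeans(values[, ref, drop = FALSE])
    values[, in_p] <- values[, in_p, drop = FALSE] - ref_mean
  }
  compendium(values, md)
}

#' Advisory outlier screen by hierarchical clustering
#'
#' Average-linkage clustering of samples on correlation distance
#' (1 - Pearson r), cut at `cut_height`; samples falling into singleton
#' clusters are reported as atypical expression profiles.  This is an
#' advisory report only -- nothing is excluded automatically, because no
#' principled cut criterion exists without inspecting the dendrogram.
#'
#' @param x a [compendium()].
#' @param cut_height dendrogram cut height on the 1 - r scale.
#' @return a list with the `hclust` object, the flat `clusters`, and
#'   `flagged` singleton sample ids.
#' @export
sample_outlier_report <- function(x, cut_height = 0.5) {
  stopifnot(inherits(x, "compendium"))
  d <- stats::as.dist(1 - cor(x$values))
  hc <- stats::hclust(d, method = "average")
  cl <- stats::cutree(hc, h = cut_height)
  sizes <- table(cl)
  flagged <- names(cl)[cl %in% as.integer(names(sizes)[sizes == 1])]
  list(hclust = hc, clusters = cl, flagged = flagged)
}
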