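#' D'Agostino K-squared normality test
#'
#' Omnibus test combining the transformed sample skewness (D'Agostino 1970)
#' and kurtosis (Anscombe & Glynn 1983) statistics; K2 = Z1^2 + Z2^2 is
#' chi-squared with 2 degrees of freedom under normality.  Used internally
#' to decide when the bulk of a gene-weight vector looks Gaussian.
#'
#' @param x numeric vector, n >= 9.
#' @return list with `statistic` (K2) and `p_value`.
#' @export
dagostino_k2 <- function(x) {
  n <- length(x)
  if (n < 9) stop("dagostino_k2 requires n >= 9", call. = FALSE)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("constant input to dagostino_k2", call. = FALSE)
  g1 <- mean((x - m)^3) / m2^1.5
  g2 <- mean((x - m)^4) / m2^2 - 3

  # skewness: D'Agostino's Z1
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis: Anscombe-Glynn Z2
  eg2 <- -6 / (n + 1)                      # E[g2] for population-moment g2
  vg2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (g2 - eg2) / sqrt(vg2)
  sqrt_b1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqrt_b1 * (2 / sqrt_b1 + sqrt(1 + 4 / sqrt_b1^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z1^2 + z2^2
  list(statistic = k2, p_value = stats::pchisq(k2, df = 2,
                                               lower.tail = FALSE))
}

#' Threshold a gene-weight vector into iModulon membership
#'
#' Default method (`"dagostino"`) iteratively strips the largest-magnitude
#' genes until the remaining weights pass a D'Agostino K-squared normality
#' test (p above `p_cutoff`); the stripped genes are the members, and the
#' threshold is placed between the smallest stripped and largest surviving
#' absolute weight so that members are exactly the genes strictly above it.
#' The `"quantile"` method uses `mean(w) + c_sd * sd(w)` on absolute
#' deviation from the mean.
#'
#' @param weights named numeric vector of gene weights (>= 10 genes).
#' @param method `"dagostino"` or `"quantile"`.
#' @param p_cutoff normality p-value above which the remainder is accepted
#'   as Gaussian (default 1e-4).
#' @param c_sd multiplier for the quantile method.
#' @return list with `threshold` (>= 0), `members` (character vector; empty
#'   when the weights already look Gaussian, in which case `degenerate` is
#'   TRUE), `method`, and `degenerate`.
#' @export
threshold_gene_weights <- function(weights, method = c("dagostino",
                                                       "quantile"),
                                   p_cutoff = 1e-4, c_sd = 3) {
  method <- match.arg(method)
  if (length(weights) < 10)
    stop("thresholding needs >= 10 genes", call. = FALSE)
  if (is.null(names(weights)))
    names(weights) <- sprintf("g%04d", seq_along(weights))
  if (length(unique(weights)) == 1)
    stop("all gene weights identical; degenerate component", call. = FALSE)

  if (method == "quantile") {
    mu <- mean(weights)
    threshold <- c_sd * sd(weights)
    members <- names(weights)[abs(weights - mu) > threshold]
    return(list(threshold = threshold, members = members,
                method = method, degenerate = length(members) == 0))
  }

  ord <- order(abs(weights), decreasing = TRUE)
  w <- weights[ord]
  n_removed <- 0
  repeat {
    remaining <- w[(n_removed + 1):length(w)]
    if (length(remaining) < 9 || length(unique(remaining)) < 3) break
    if (dagostino_k2(remaining)$p_value > p_cutoff) break
    n_removed <- n_removed + 1
  }
  if (n_removed == 0) {
    return(list(threshold = max(abs(weights)), members = character(),
                method = method, degenerate = TRUE))
  }
  lo <- abs(w[n_removed])                 # smallest removed |weight|
  hi <- if (n_removed < length(w)) abs(w[n_removed + 1]) else 0
  threshold <- (lo + hi) / 2
  members <- names(weights)[abs(weights) > threshold]
  list(threshold = threshold, members = members, method = method,
       degenerate = FALSE)
}

#' Explained variance of a component subset
#'
#' Fraction of total variance in the (centered) expression matrix captured
#' by a subset S of components:
#' `1 - ||X - M_S A_S||_F^2 / ||X||_F^2`.
#'
#' @param x a [compendium()] or numeric matrix.
#' @param M gene-weight matrix (genes x components).
#' @param A activity matrix (components x samples).
#' @param subset component indices; default all. An empty subset gives 0.
#' @return explained-variance fraction.
#' @export
explained_variance <- function(x, M, A, subset = NULL) {
  X <- as_expression_matrix(x)
  if (frobenius(X) == 0) stop("zero expression matrix", call. = FALSE)
  if (is.null(subset)) subset <- seq_len(ncol(M))
  if (length(subset) == 0) return(0)
  if (any(subset < 1 | subset > ncol(M)))
    stop("component subset out of range", call. = FALSE)
  R <- X - M[, subset, drop = FALSE] %*% A[subset, , drop = FALSE]
  1 - frobenius(R)^2 / frobenius(X)^2
}

#' Is a component a single-gene iModulon?
#'
#' TRUE when the thresholded membership holds exactly one gene, or the top
#' gene's squared weight carries at least half the column's total squared
#' weight (a component dominated by a single high-coefficient gene).
#'
#' @param weights the component's gene-weight vector.
#' @param members thresholded member genes (character vector).
#' @return logical flag.
#' @export
detect_single_gene <- function(weights, members) {
  length(members) == 1 ||
    max(weights^2) >= 0.5 * sum(weights^2)
}

#' Extract iModulons from a robust decomposition
#'
#' Thresholds every component of an `ica_decomposition`, computes each
#' component's explained variance (as a singleton subset), and assigns a
#' provisional category: `single-gene` for dominance by one gene,
#' `uncharacterized` otherwise (enrichment may later upgrade components to
#' `regulatory`).  Components whose weights already look Gaussian are kept
#' with empty membership and flagged degenerate.
#'
#' @param x the (centered) [compendium()] or matrix the decomposition was
#'   fit to.
#' @param decomposition an `ica_decomposition`.
#' @param method,p_cutoff passed to [threshold_gene_weights()].
#' @return an `imodulon_set`: list of iModulons (each with `name`,
#'   `component_index`, `gene_weights`, `threshold`, `member_genes`,
#'   `explained_variance`, `category`, `enrichment`) plus a `summary`
#'   data.frame.
#' @export
extract_imodulons <- function(x, decomposition, method = "dagostino",
                              p_cutoff = 1e-4) {
  stopifnot(inherits(decomposition, "ica_decomposition"))
  M <- decomposition$M
  A <- decomposition$A
  mods <- lapply(seq_len(ncol(M)), function(j) {
    w <- M[, j]
    thr <- threshold_gene_weights(w, method = method, p_cutoff = p_cutoff)
    sg <- detect_single_gene(w, thr$members)
    list(name = colnames(M)[j],
         component_index = j,
         gene_weights = w,
         threshold = thr$threshold,
         member_genes = thr$members,
         degenerate = thr$degenerate,
         explained_variance = explained_variance(x, M, A, subset = j),
         category = if (sg) "single-gene" else "uncharacterized",
         enrichment = NULL)
  })
  names(mods) <- colnames(M)
  summary <- data.frame(
    name = vapply(mods, `[[`, "", "name"),
    n_genes = vapply(mods, function(m) length(m$member_genes), 1L),
    threshold = vapply(mods, `[[`, 1.0, "threshold"),
    explained_variance = vapply(mods, `[[`, 1.0, "explained_variance"),
    category = vapply(mods, `[[`, "", "category"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(imodulons = mods, summary = summary),
            class = "imodulon_set")
}

#' @export
print.imodulon_set <- function(x, ...) {
  cat(sprintf("<imodulon_set> %d iModulons (%d single-gene), total EV %.3f\n",
              length(x$imodulons),
              sum(x$summary$category == "single-gene"),
              sum(x$summary$explained_variance)))
  invisible(x)
}

#' Correlate and cluster iModulon activities
#'
#' Pairwise Spearman correlation of activity rows, average-linkage
#' hierarchical clustering on `1 - r`, and flat clusters with their mean
#' within-cluster Spearman R.
#'
#' @param A activity matrix (components x samples), >= 2 components.
#' @param cut_height flat-cluster cut on the 1 - r scale.
#' @param linkage linkage method for [stats::hclust()].
#' @return list with `correlation`, `hclust`, `clusters` (named integer
#'   vector) and `cluster_summary` (cluster, size, mean_spearman_r).
#' @export
correlate_and_cluster_imodulons <- function(A, cut_height = 0.8,
                                            linkage = "average") {
  if (nrow(A) < 2) stop("need >= 2 components", call. = FALSE)
  const <- apply(A, 1, function(r) sd(r) == 0)
  if (any(const))
    stop("constant activity row(s): ",
         paste(rownames(A)[const], collapse = ", "), call. = FALSE)
  r <- cor(t(A), method = "spearman")
  hc <- stats::hclust(stats::as.dist(1 - r), method = linkage)
  cl <- stats::cutree(hc, h = cut_height)
  summ <- do.call(rbind, lapply(sort(unique(cl)), function(k) {
    members <- which(cl == k)
    mean_r <- if (length(members) > 1) {
      sub <- r[members, members]
      mean(sub[upper.tri(sub)])
    } else NA_real_
    data.frame(cluster = k, size = length(members),
               mean_spearman_r = mean_r)
  }))
  list(correlation = r, hclust = hc, clusters = cl,
       cluster_summary = summ)
}

#' Differential iModulon activity (DIMA)
#'
#' Contrasts mean component activities between two sample groups.  The null
#' distribution of activity differences is fitted as a log-normal on the
#' absolute activity differences between biological replicate pairs (the
#' only samples whose differences are pure noise); each component's p-value
#' is the fitted upper-tail probability of its |difference|, and
#' Benjamini-Hochberg FDR at `alpha` marks significance.
#'
#' The replicate fit describes the noise of a single-sample difference; the
#' tested statistic is a difference of group means, so the fitted location
#' is rescaled by `sqrt((1/n1 + 1/n2) / 2)` to match the statistic's
#' sampling variance (no change for single-sample groups).
#'
#' @param A activity matrix (components x samples).
#' @param group1,group2 disjoint, non-empty character vectors of sample ids.
#' @param replicate_pairs two-column matrix/data.frame of replicate sample
#'   ids used to fit the null; see [replicate_pairs_from_metadata()].
#' @param null_params optional explicit c(meanlog, sdlog) overriding the
#'   replicate fit; taken as already on the scale of the tested contrast
#'   (no group-size rescaling applied).
#' @param alpha FDR level.
#' @return data.frame (component, delta_activity, p_value, q_value,
#'   significant) with the fitted null in attribute `null_params`.
#' @export
differential_activity <- function(A, group1, group2,
                                  replicate_pairs = NULL,
                                  null_params = NULL, alpha = 0.05) {
  stopifnot(is.matrix(A))
  if (!length(group1) || !length(group2))
    stop("both groups must be non-empty", call. = FALSE)
  if (length(intersect(group1, group2)))
    stop("groups must be disjoint", call. = FALSE)
  missing <- setdiff(c(group1, group2), colnames(A))
  if (length(missing))
    stop("samples not in activity matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)

  delta <- rowMeans(A[, group2, drop = FALSE]) -
    rowMeans(A[, group1, drop = FALSE])

  if (is.null(null_params)) {
    if (is.null(replicate_pairs) || !nrow(replicate_pairs))
      stop("no replicate pairs for null fitting; pass explicit ",
           "`null_params = c(meanlog, sdlog)`", call. = FALSE)
    diffs <- abs(unlist(lapply(seq_len(nrow(replicate_pairs)), function(i) {
      A[, replicate_pairs[i, 1]] - A[, replicate_pairs[i, 2]]
    })))
    diffs <- diffs[diffs > 0]
    if (length(diffs) < 3)
      stop("too few non-zero replicate differences to fit a null",
           call. = FALSE)
    # rescale from single-pair differences to the group-mean contrast
    size_factor <- sqrt((1 / length(group1) + 1 / length(group2)) / 2)
    null_params <- c(meanlog = mean(log(diffs)) + log(size_factor),
                     sdlog = sd(log(diffs)))
  }

  p <- ifelse(abs(delta) == 0, 1,
              stats::plnorm(abs(delta), meanlog = null_params[1],
                            sdlog = null_params[2], lower.tail = FALSE))
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(component = rownames(A), delta_activity = delta,
                    p_value = p, q_value = q, significant = q < alpha,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "null_params") <- null_params
  out
}

#' Enumerate replicate sample pairs from metadata
#'
#' All within-(project, condition) sample pairs, the empirical noise pairs
#' used to fit the DIMA null.
#'
#' @param metadata sample metadata (see [compendium()]).
#' @return two-column character matrix of sample-id pairs.
#' @export
replicate_pairs_from_metadata <- function(metadata) {
  metadata <- validate_metadata(metadata)
  grp <- split(metadata$sample_id,
               paste(metadata$project, metadata$condition, sep = "\r"))
  pairs <- list()
  for (g in grp) {
    if (length(g) < 2) next
    idx <- utils::combn(length(g), 2)
    for (j in seq_len(ncol(idx)))
      pairs[[length(pairs) + 1L]] <- c(g[idx[1, j]], g[idx[2, j]])
  }
  do.call(rbind, pairs)
}
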