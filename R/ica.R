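#' Robust independent component analysis of an expression compendium
#'
#' Decomposes a centered genes x samples matrix `X` as `X ~ M A`, where the
#' columns of `M` are statistically independent, typically sparse gene-weight
#' vectors and `A` holds per-sample component activities.  The fixed-point
#' (FastICA-type) algorithm with a log-cosh contrast is run `n_restarts`
#' times from random rotations of a shared SVD whitening; components pooled
#' across restarts are clustered by the distance `1 - |Pearson r|` between
#' gene-weight vectors, and only clusters supported by at least half the
#' restarts survive.  Each surviving cluster is represented by its
#' centrotype (the member minimizing summed distance to the rest).  The
#' activity matrix is recomputed as the least-squares projection of `X`
#' onto the final `M`, so `M %*% A` reconstructs `X` up to the discarded
#' subspace.
#'
#' @param x a [compendium()] (reference-centered; a warning is issued if the
#'   reference groups are visibly off zero) or a plain numeric matrix.
#' @param dimension number of components requested
#'   (<= min(genes, samples)).
#' @param n_restarts independent FastICA runs pooled for robustness.
#' @param seed master seed; restart seeds are derived from it.
#' @param eps clustering radius on the 1 - |r| scale.
#' @param min_support minimum restarts supporting a robust component;
#'   default `ceiling(n_restarts / 2)`.
#' @param max_iter,tol fixed-point iteration controls.
#' @return an `ica_decomposition`: `M` (genes x components, unit-norm
#'   columns, largest-magnitude weight positive), `A` (components x
#'   samples), `cluster_sizes`, `n_restarts`, `dimension`, `seed`.
#' @export
run_ica <- function(x, dimension, n_restarts = 10, seed = 1,
                    eps = 0.2, min_support = NULL,
                    max_iter = 1000, tol = 1e-6) {
  X <- as_expression_matrix(x, warn_uncentered = TRUE)
  dimension <- check_count(dimension, "dimension", 1)
  n_restarts <- check_count(n_restarts, "n_restarts", 1)
  if (dimension > min(dim(X)))
    stop("dimension exceeds min(genes, samples)", call. = FALSE)
  if (is.null(min_support)) min_support <- ceiling(n_restarts / 2)

  # shared whitening: top-`dimension` left singular vectors span the
  # subspace searched by every restart.  X is taken as already centered
  # (reference-condition centering); no further centering is applied, so
  # M %*% A reconstructs X itself up to the discarded subspace.
  sv <- svd(X, nu = dimension, nv = 0)
  if (sv$d[dimension] < 1e-12 * sv$d[1])
    stop("matrix rank is below the requested dimension", call. = FALSE)
  Z <- t(sv$u) * sqrt(nrow(X))  # dimension x genes, unit-variance rows

  pool <- vector("list", n_restarts)
  for (r in seq_len(n_restarts)) {
    W <- with_seed(derive_seed(seed, paste0("ica-restart-", r)), {
      random_orthonormal(dimension)
    })
    W <- fastica_fixed_point(Z, W, max_iter = max_iter, tol = tol)
    S <- t(W %*% Z)                       # genes x dimension
    pool[[r]] <- normalize_components(S)
  }
  P <- do.call(cbind, pool)

  D <- 1 - abs(suppressWarnings(cor(P)))
  D[is.na(D)] <- 1
  labels <- dbscan_distance(D, eps = eps, min_pts = min_support)
  keep <- integer(0)
  sizes <- integer(0)
  for (cl in setdiff(unique(labels), 0L)) {
    members <- which(labels == cl)
    if (length(members) < min_support) next
    centro <- members[which.min(rowSums(D[members, members, drop = FALSE]))]
    keep <- c(keep, centro)
    sizes <- c(sizes, length(members))
  }

  M <- P[, keep, drop = FALSE]
  rownames(M) <- rownames(X)
  if (ncol(M)) {
    M <- normalize_components(M)
    A <- qr.coef(qr(M), X)
    colnames(A) <- colnames(X)
    # order components by activity variance (explained signal), largest first
    ord <- order(apply(A, 1, function(a) sum(a^2)), decreasing = TRUE)
    M <- M[, ord, drop = FALSE]
    A <- A[ord, , drop = FALSE]
    sizes <- sizes[ord]
    colnames(M) <- rownames(A) <- sprintf("IC%02d", seq_len(ncol(M)))
  } else {
    A <- matrix(0, 0, ncol(X), dimnames = list(NULL, colnames(X)))
  }
  structure(list(M = M, A = A, n_restarts = n_restarts,
                 cluster_sizes = sizes, dimension = dimension,
                 seed = as.integer(seed)),
            class = "ica_decomposition")
}

#' @export
print.ica_decomposition <- function(x, ...) {
  cat(sprintf(
    "<ica_decomposition> %d robust components (dimension %d, %d restarts)\n",
    ncol(x$M), x$dimension, x$n_restarts))
  invisible(x)
}

# Accept a compendium or a bare matrix; optionally warn when the
# project-reference groups are not centered on zero.
as_expression_matrix <- function(x, warn_uncentered = FALSE) {
  if (inherits(x, "compendium")) {
    if (warn_uncentered) {
      md <- x$metadata
      ref <- md$is_reference
      if (any(ref)) {
        for (p in unique(md$project[ref])) {
          m <- rowMeans(x$values[, md$project == p & ref, drop = FALSE])
          if (max(abs(m)) > 1e-6) {
            warning("compendium does not look reference-centered; ",
                    "run center_to_reference() first", call. = FALSE)
            break
          }
        }
      }
    }
    x$values
  } else if (is.matrix(x) && is.numeric(x)) {
    x
  } else stop("expected a compendium or numeric matrix", call. = FALSE)
}

# Random orthonormal d x d matrix (QR of a Gaussian matrix).
random_orthonormal <- function(d) {
  qr.Q(qr(matrix(rnorm(d * d), d, d)))
}

# Symmetric FastICA fixed-point iterations with the log-cosh contrast.
# Z: components x observations whitened data; W: initial rotation.
fastica_fixed_point <- function(Z, W, max_iter = 1000, tol = 1e-6,
                                alpha = 1) {
  n <- ncol(Z)
  W <- sym_decorrelate(W)
  for (it in seq_len(max_iter)) {
    U <- W %*% Z
    G <- tanh(alpha * U)
    gprime_mean <- alpha * rowMeans(1 - G^2)
    W1 <- (G %*% t(Z)) / n - gprime_mean * W
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) break
  }
  W
}

# W <- (W W')^{-1/2} W via eigendecomposition.
sym_decorrelate <- function(W) {
  e <- eigen(W %*% t(W), symmetric = TRUE)
  vals <- pmax(e$values, .Machine$double.eps)
  e$vectors %*% diag(1 / sqrt(vals), length(vals)) %*% t(e$vectors) %*% W
}

# Unit-norm columns with the largest-magnitude entry positive.
normalize_components <- function(S) {
  nrm <- sqrt(colSums(S^2))
  nrm[nrm == 0] <- 1
  S <- sweep(S, 2, nrm, "/")
  flip <- vapply(seq_len(ncol(S)), function(j) {
    sign(S[which.max(abs(S[, j])), j])
  }, numeric(1))
  flip[flip == 0] <- 1
  sweep(S, 2, flip, "*")
}

# Plain DBSCAN on a precomputed distance matrix; returns integer labels,
# 0 marking noise points.
dbscan_distance <- function(D, eps, min_pts) {
  n <- nrow(D)
  nb <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- vapply(nb, length, 1L) >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      j <- queue[[1]]
      queue <- queue[-1]
      for (q in nb[[j]]) {
        if (labels[q] == 0L) {
          labels[q] <- cl
          if (core[q]) queue <- c(queue, q)
        }
      }
    }
  }
  labels
}

#' Sweep candidate ICA dimensionalities
#'
#' Runs [run_ica()] at each requested dimension and tabulates, per
#' dimension, the number of robust components and how many of them are
#' single-gene components after thresholding (see [detect_single_gene()]).
#' Errors at individual dimensions are recorded and the sweep continues.
#'
#' @param x a [compendium()] or numeric matrix (centered).
#' @param dims strictly increasing integer vector of dimensions.
#' @param n_restarts,seed passed to [run_ica()] (per-dimension seeds are
#'   derived from `seed`).
#' @param threshold_method passed to [threshold_gene_weights()].
#' @return a `dimension_sweep` data.frame with columns `dimension`,
#'   `n_robust_components`, `n_single_gene_components`,
#'   `n_non_single_gene`, `error`.
#' @export
sweep_dimensions <- function(x, dims, n_restarts = 10, seed = 1,
                             threshold_method = "dagostino") {
  if (!length(dims) || any(diff(dims) <= 0))
    stop("`dims` must be non-empty and strictly increasing", call. = FALSE)
  rows <- lapply(dims, function(d) {
    res <- tryCatch(
      run_ica(x, dimension = d, n_restarts = n_restarts,
              seed = derive_seed(seed, paste0("sweep-", d))),
      error = function(e) e)
    if (inherits(res, "error"))
      return(data.frame(dimension = d, n_robust_components = NA_integer_,
                        n_single_gene_components = NA_integer_,
                        n_non_single_gene = NA_integer_,
                        error = conditionMessage(res),
                        stringsAsFactors = FALSE))
    # degenerate components (weights already Gaussian, no members) fail to
    # define a multi-gene set just as single-gene components do; both count
    # against the dimension
    n_single <- 0L
    for (j in seq_len(ncol(res$M))) {
      thr <- threshold_gene_weights(res$M[, j], method = threshold_method)
      if (thr$degenerate || detect_single_gene(res$M[, j], thr$members))
        n_single <- n_single + 1L
    }
    data.frame(dimension = d, n_robust_components = ncol(res$M),
               n_single_gene_components = n_single,
               n_non_single_gene = ncol(res$M) - n_single,
               error = NA_character_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("dimension_sweep", class(out))
  out
}

#' Select the optimal ICA dimensionality from sweep statistics
#'
#' The working criterion: a dimensionality is optimal when every robust
#' component is a multi-gene component, i.e. the number of non-single-gene
#' components equals the number of robust components.  Under-decomposition
#' trivially satisfies the equality (mixtures of modules are never
#' single-gene), while over-decomposition breaks it as stable single-gene
#' components start absorbing surplus dimensions; the largest dimension
#' still satisfying the equality therefore sits at the boundary and is
#' returned.  When no dimension satisfies it exactly, the dimension
#' minimizing the single-gene excess is returned (ties broken toward the
#' smaller dimension) and flagged approximate.
#'
#' @param stats a `dimension_sweep` from [sweep_dimensions()].
#' @return the selected dimension (integer) with attribute `approximate`.
#' @export
select_optimal_dimension <- function(stats) {
  if (!is.data.frame(stats) || !nrow(stats))
    stop("empty dimension sweep", call. = FALSE)
  ok <- stats[!is.na(stats$n_robust_components) &
                stats$n_robust_components > 0, , drop = FALSE]
  if (!nrow(ok))
    stop("no dimension yielded robust components", call. = FALSE)
  exact <- ok$n_non_single_gene == ok$n_robust_components
  if (any(exact)) {
    d <- max(ok$dimension[exact])
    attr(d, "approximate") <- FALSE
  } else {
    excess <- ok$n_robust_components - ok$n_non_single_gene
    d <- ok$dimension[which.min(excess)]  # which.min takes the first = smallest
    attr(d, "approximate") <- TRUE
  }
  d
}

#' Write the M and A matrices as TSV files
#'
#' @param decomposition an `ica_decomposition`.
#' @param m_path,a_path output paths for the gene-weight and activity
#'   matrices (genes/components as rows, labelled).
#' @return the decomposition, invisibly.
#' @export
write_ica_matrices <- function(decomposition, m_path, a_path) {
  stopifnot(inherits(decomposition, "ica_decomposition"))
  write_labelled_matrix(decomposition$M, m_path, "gene_id")
  write_labelled_matrix(decomposition$A, a_path, "component")
  invisible(decomposition)
}

write_labelled_matrix <- function(m, path, label) {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- label
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
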