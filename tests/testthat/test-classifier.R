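simple_operon_map <- function(n_operons, genes_per_operon = 2) {
  n <- n_operons * genes_per_operon
  genes <- data.frame(
    gene_id = sprintf("g%04d", 1:n),
    accession = "A",
    start = seq(1, by = 2000, length.out = n),
    end = seq(1, by = 2000, length.out = n) + 900,
    strand = "+")
  # genes of one operon adjacent, big gaps between operons handled by ids
  om <- cluster_operons(genes, gap_threshold = 1e9)
  # rebuild deterministically: assign consecutive pairs to operons
  tab <- om$table
  tab$operon_id <- rep(sprintf("A_op%04d", seq_len(n_operons)),
                       each = genes_per_operon)
  structure(list(table = tab,
                 gene_to_operon = setNames(tab$operon_id, tab$gene_id)),
            class = "operon_map")
}

test_that("operon-grouped folds partition operons evenly and stratify labels", {
  om <- simple_operon_map(10)
  labels <- setNames(rep(c(1, 0), c(10, 10)), om$table$gene_id)
  folds <- operon_grouped_folds(labels, om, k = 5, seed = 1)
  expect_equal(as.integer(table(folds$operon_folds)), rep(2L, 5))
  # partition contract: each operon in exactly one fold
  expect_setequal(names(folds$operon_folds), unique(om$table$operon_id))
  # genes inherit their operon's fold
  op_of_gene <- om$table$operon_id[match(names(folds$gene_folds),
                                         om$table$gene_id)]
  expect_identical(unname(folds$gene_folds),
                   unname(folds$operon_folds[op_of_gene]))
  lab2 <- setNames(rep(c(1, 0), c(4, 16)), om$table$gene_id)
  expect_error(operon_grouped_folds(lab2, om, k = 5), "positive operons")
})

test_that("fold stratification keeps per-fold positives within one operon of parity", {
  om <- simple_operon_map(20)
  labels <- setNames(as.integer(om$table$operon_id %in%
                                  sprintf("A_op%04d", 1:8)),
                     om$table$gene_id)
  for (s in 1:25) {
    folds <- operon_grouped_folds(labels, om, k = 5, seed = s)
    op_label <- tapply(labels, om$gene_to_operon[names(labels)],
                       function(v) any(v == 1))
    per_fold <- tapply(op_label[names(folds$operon_folds)],
                       folds$operon_folds, sum)
    expect_true(all(abs(per_fold - 8 / 5) <= 1))
  }
})

test_that("balanced input with no Tomek links passes through resampling unchanged", {
  X <- matrix(c(0, 0, 1, 1, 10, 10, 11, 11), ncol = 1)
  y <- c(0, 0, 0, 0, 1, 1, 1, 1)
  rs <- resample_balanced(X, y, k_neighbors = 2, seed = 1)
  expect_identical(rs$labels, as.integer(y))
  expect_equal(rs$features, X)
  expect_identical(rs$n_tomek_pairs, 0L)
})

test_that("SMOTE synthetics lie on segments between minority neighbours", {
  withr::with_seed(3, {
    X <- rbind(matrix(rnorm(40, mean = 0), ncol = 2),
               matrix(rnorm(12, mean = 4), ncol = 2))
    y <- rep(c(0, 1), c(20, 6))
    rs <- resample_balanced(X, y, k_neighbors = 3, seed = 5)
    syn <- rs$features[rs$is_synthetic, , drop = FALSE]
    Xmin <- X[y == 1, , drop = FALSE]
    for (i in seq_len(nrow(syn))) {
      on_segment <- FALSE
      for (a in seq_len(nrow(Xmin))) for (b in seq_len(nrow(Xmin))) {
        if (a == b) next
        v <- Xmin[b, ] - Xmin[a, ]
        w <- syn[i, ] - Xmin[a, ]
        t <- sum(w * v) / sum(v * v)
        if (t >= -1e-9 && t <= 1 + 1e-9 &&
            sqrt(sum((w - t * v)^2)) < 1e-8) on_segment <- TRUE
      }
      expect_true(on_segment)
    }
    # class counts equal after balancing (up to removed Tomek pairs)
    counts <- table(rs$labels)
    expect_lte(abs(counts["0"] - counts["1"]), 2 * rs$n_tomek_pairs)
  })
})

test_that("Tomek links match an exhaustive mutual-nearest-neighbour oracle", {
  withr::with_seed(7, {
    X <- matrix(rnorm(200), ncol = 2)
    y <- rep(c(0, 1), each = 50)
    # oracle: O(n^2) mutual 1-NN of opposite class
    D <- as.matrix(dist(X)); diag(D) <- Inf
    nn <- apply(D, 1, which.min)
    oracle_pairs <- 0
    for (i in seq_len(nrow(X))) {
      j <- nn[i]
      if (j > i && nn[j] == i && y[i] != y[j]) oracle_pairs <- oracle_pairs + 1
    }
    rs <- resample_balanced(X, y, k_neighbors = 5, seed = 9)
    expect_identical(rs$n_tomek_pairs, as.integer(oracle_pairs))
    expect_equal(nrow(rs$features), nrow(X) - 2 * oracle_pairs)
  })
  expect_error(resample_balanced(matrix(1:4, 2), c(1, 1)), "classes")
  expect_error(resample_balanced(matrix(rnorm(20), 10), rep(c(0, 1), c(8, 2)),
                                 k_neighbors = 5), "k_neighbors")
})

test_that("elastic-net logistic fits point along the separating direction", {
  X <- matrix(c(rnorm(30, -2), rnorm(30, 2)), ncol = 1)
  y <- rep(c(0, 1), each = 30)
  fit <- fit_elastic_net_logistic(X, y, regularization_strength = 0.01)
  expect_gt(fit$coefficients[1], 0)
  # overwhelming regularization shrinks coefficients to zero
  fit0 <- fit_elastic_net_logistic(X, y, regularization_strength = 1e4)
  expect_equal(unname(fit0$coefficients[1]), 0, tolerance = 1e-8)
  expect_error(fit_elastic_net_logistic(matrix(c(1, NA), 2), c(0, 1)),
               "finite|class")
})

test_that("the fitted coefficients are locally optimal for the penalized objective", {
  withr::with_seed(11, {
    X <- cbind(rnorm(80), rnorm(80))
    y <- as.integer(X[, 1] + 0.5 * X[, 2] + rnorm(80, sd = 0.5) > 0)
    model <- fit_elastic_net_logistic(X, y, regularization_strength = 0.05)
    beta_std <- model$coefficients * model$scale
    int_std <- model$intercept + sum(model$coefficients * model$center)
    base <- elastic_net_objective(model, X, y)
    worse <- vapply(1:300, function(i) {
      pert <- beta_std + rnorm(2, sd = 0.05)
      elastic_net_objective(model, X, y, beta = pert, intercept = int_std)
    }, 1.0)
    expect_true(all(worse >= base - 1e-6))
  })
})

test_that("rank AUC equals exhaustive pairwise concordance", {
  withr::with_seed(13, {
    for (i in 1:10) {
      scores <- sample(seq(0, 1, 0.1), 50, replace = TRUE)  # with ties
      labels <- rbinom(50, 1, 0.4)
      if (length(unique(labels)) < 2) next
      expect_equal(auc_rank(scores, labels),
                   oracle_auc_pairs(scores, labels))
    }
  })
  expect_true(is.na(auc_rank(1:5, rep(1, 5))))
})

test_that("a perfectly informative feature yields mean AUC 1", {
  om <- simple_operon_map(15)
  labels <- setNames(as.integer(om$table$operon_id %in%
                                  sprintf("A_op%04d", 1:5)),
                     om$table$gene_id)
  X <- matrix(labels + withr::with_seed(1, rnorm(length(labels), sd = 0.01)),
              ncol = 1, dimnames = list(names(labels), "f"))
  rep <- evaluate_cv(X, labels, om, k = 5, seed = 3)
  expect_equal(rep$mean_auc, 1)
  expect_true(rep$passed_benchmark)
  expect_length(rep$fold_aucs, 5)
})

test_that("grouped splitting does not inflate AUC the way i.i.d. splitting can", {
  # operon-mates share identical features; with noise-only signal an
  # i.i.d. gene split leaks operon identity into the test folds
  grouped <- c(); leaky <- c()
  for (s in 1:8) {
    om <- simple_operon_map(30, genes_per_operon = 3)
    ops <- unique(om$table$operon_id)
    pos_ops <- withr::with_seed(s, sample(ops, 8))
    labels <- setNames(as.integer(om$table$operon_id %in% pos_ops),
                       om$table$gene_id)
    feat <- withr::with_seed(s + 100, rnorm(length(ops)))  # pure noise
    X <- matrix(feat[match(om$table$operon_id, ops)], ncol = 1,
                dimnames = list(om$table$gene_id, "f"))
    grouped <- c(grouped, evaluate_cv(X, labels, om, seed = s)$mean_auc)
    leaky <- c(leaky, evaluate_cv(X, labels, om, seed = s,
                                  group_by_operon = FALSE)$mean_auc)
  }
  expect_lt(mean(grouped), mean(leaky))
})
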