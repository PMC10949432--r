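test_that("the K-squared normality test matches independently computed reference values", {
  # reference statistics computed with an independent implementation of the
  # same published formulas (frozen)
  x <- withr::with_seed(42, rnorm(50))
  r <- dagostino_k2(x)
  expect_equal(r$statistic, 0.6863994613, tolerance = 1e-9)
  expect_equal(r$p_value, 0.70949648923, tolerance = 1e-9)
  y <- withr::with_seed(42, {rnorm(50); rexp(100)})
  r2 <- dagostino_k2(y)
  expect_equal(r2$statistic, 63.9402104316, tolerance = 1e-9)
  expect_equal(r2$p_value, 1.3048473831e-14, tolerance = 1e-6)
  expect_error(dagostino_k2(rep(1, 20)), "constant")
})

test_that("thresholding recovers planted outlier genes exactly", {
  w <- withr::with_seed(5, rnorm(200, sd = 0.1))
  names(w) <- sprintf("g%03d", 1:200)
  outliers <- c("g003", "g050", "g101", "g150", "g199")
  w[outliers] <- c(0.9, -1.1, 1.0, -0.95, 1.2)
  thr <- threshold_gene_weights(w)
  expect_setequal(thr$members, outliers)
  expect_false(thr$degenerate)
  # membership invariant under global sign flip
  expect_setequal(threshold_gene_weights(-w)$members, outliers)
})

test_that("already-Gaussian weights yield an empty, flagged membership", {
  w <- withr::with_seed(9, rnorm(300, sd = 0.05))
  thr <- threshold_gene_weights(w)
  expect_length(thr$members, 0)
  expect_true(thr$degenerate)
  expect_error(threshold_gene_weights(rnorm(5)), ">= 10")
  expect_error(threshold_gene_weights(rep(0.5, 50)), "identical")
})

test_that("the quantile thresholding fallback flags symmetric outliers", {
  w <- withr::with_seed(11, rnorm(100, sd = 0.1))
  names(w) <- sprintf("g%03d", 1:100)
  w[c(1, 2)] <- c(2, -2)
  thr <- threshold_gene_weights(w, method = "quantile")
  expect_setequal(thr$members, c("g001", "g002"))
})

test_that("explained variance follows the Frobenius residual definition", {
  # toy 4x4: direct arithmetic oracle
  X <- matrix(c(2, 0, 1, -1,  0, 3, 0, 1,  1, 1, 1, 1,  -1, 0, 2, 0), 4, 4)
  M <- matrix(c(1, 0, 0, 0), 4, 1)
  A <- matrix(c(2, 0, 1, -1), 1, 4)
  resid <- X - M %*% A
  expect_equal(explained_variance(X, M, A),
               1 - sum(resid^2) / sum(X^2))
  expect_identical(explained_variance(X, M, A, subset = integer(0)), 0)
  expect_error(explained_variance(matrix(0, 2, 2), M, A), "zero")

  # noiseless planted data with all components: essentially full recovery
  sim <- generate_compendium(100, 10, 2, 3, noise_sd = 0,
                             replicate_rho = 0.9, seed = 3)
  xc <- center_to_reference(sim$compendium)
  dec <- run_ica(xc, 3, 5, seed = 1)
  expect_gte(explained_variance(xc, dec$M, dec$A), 0.999)
})

test_that("subset explained variance is superadditive on disjoint singletons", {
  sim <- generate_compendium(100, 10, 2, 3, noise_sd = 0.4,
                             replicate_rho = 0.9, seed = 13)
  xc <- center_to_reference(sim$compendium)
  dec <- run_ica(xc, 3, 5, seed = 1)
  singles <- vapply(seq_len(ncol(dec$M)), function(j)
    explained_variance(xc, dec$M, dec$A, j), 1.0)
  total <- explained_variance(xc, dec$M, dec$A)
  # equality would require exactly orthogonal components; allow the small
  # slack their residual correlation introduces
  expect_lte(sum(singles), total + 0.01)
  expect_lte(total, 1)
})

test_that("single-gene detection triggers on dominance or singleton membership", {
  w <- c(10, rnorm(99, sd = 0.1))
  expect_true(detect_single_gene(w, "g1"))
  expect_true(detect_single_gene(w, c("g1", "g2")))   # dominance clause
  eq <- rep(1, 10)
  expect_false(detect_single_gene(eq, sprintf("g%d", 1:10)))
})

test_that("activity correlation clustering groups duplicated components", {
  A <- withr::with_seed(21, matrix(rnorm(5 * 40), 5, 40))
  rownames(A) <- sprintf("IC%02d", 1:5)
  A[5, ] <- A[1, ]                                   # exact duplicate
  res <- correlate_and_cluster_imodulons(A, cut_height = 0.2)
  expect_equal(res$correlation["IC01", "IC05"], 1)
  expect_identical(unname(res$clusters["IC01"]), unname(res$clusters["IC05"]))
  expect_equal(res$correlation, t(res$correlation))
  expect_equal(unname(diag(res$correlation)), rep(1, 5))
  # constant row is rejected by name
  A2 <- A
  A2[3, ] <- 2
  expect_error(correlate_and_cluster_imodulons(A2), "IC03")
})

test_that("independent activities show near-zero off-diagonal correlation", {
  A <- withr::with_seed(31, matrix(rnorm(6 * 500), 6, 500))
  rownames(A) <- sprintf("IC%02d", 1:6)
  r <- correlate_and_cluster_imodulons(A)$correlation
  expect_lt(mean(abs(r[upper.tri(r)])), 0.1)
})

test_that("differential activity is zero for identical groups and antisymmetric", {
  A <- withr::with_seed(41, matrix(rnorm(4 * 12), 4, 12))
  dimnames(A) <- list(sprintf("IC%02d", 1:4), sprintf("s%02d", 1:12))
  null <- c(meanlog = log(0.3), sdlog = 0.5)
  g1 <- c("s01", "s02", "s03")
  g2 <- c("s04", "s05", "s06")
  # duplicate group-1 columns into group 2's positions
  A[, g2] <- A[, g1]
  d0 <- differential_activity(A, g1, g2, null_params = null)
  expect_equal(d0$delta_activity, rep(0, 4))
  expect_true(all(d0$p_value == 1))
  # antisymmetry under group swap
  A <- withr::with_seed(43, matrix(rnorm(4 * 12), 4, 12,
                                   dimnames = dimnames(A)))
  d12 <- differential_activity(A, g1, g2, null_params = null)
  d21 <- differential_activity(A, g2, g1, null_params = null)
  expect_equal(d12$delta_activity, -d21$delta_activity)
  expect_error(differential_activity(A, g1, g1, null_params = null),
               "disjoint")
  expect_error(differential_activity(A, g1, g2), "null_params")
})

test_that("a planted activity shift is flagged while null components stay quiet", {
  res <- replicate(20, {
    A <- matrix(rnorm(5 * 12, sd = 0.3), 5, 12)
    dimnames(A) <- list(sprintf("IC%02d", 1:5), sprintf("s%02d", 1:12))
    pairs <- cbind(sprintf("s%02d", seq(1, 11, 2)),
                   sprintf("s%02d", seq(2, 12, 2)))
    g1 <- sprintf("s%02d", 1:4)
    g2 <- sprintf("s%02d", 5:8)
    A["IC01", g2] <- A["IC01", g2] + 3
    da <- differential_activity(A, g1, g2, replicate_pairs = pairs)
    c(hit = da$significant[da$component == "IC01"],
      false_flags = sum(da$significant[da$component != "IC01"]))
  })
  expect_gte(mean(res["hit", ]), 0.95)
  expect_lte(mean(res["false_flags", ]), 0.2 * 4)
})

test_that("DIMA p-values are roughly uniform under the null", {
  withr::with_seed(53, {
    ps <- c()
    for (i in 1:40) {
      A <- matrix(rnorm(10 * 62, sd = 0.3), 10, 62)
      dimnames(A) <- list(sprintf("IC%02d", 1:10), sprintf("s%02d", 1:62))
      pairs <- cbind(sprintf("s%02d", seq(1, 59, 2)),
                     sprintf("s%02d", seq(2, 60, 2)))
      # contrast two fresh single samples: their difference is a pure
      # noise draw on the same scale as the fitted replicate null
      da <- differential_activity(A, "s61", "s62",
                                  replicate_pairs = pairs)
      ps <- c(ps, da$p_value)
    }
    # the fitted log-normal approximates, but is not, the half-normal
    # difference law, so a mild departure from uniformity is expected
    ks <- suppressWarnings(stats::ks.test(ps, "punif"))
    expect_lt(unname(ks$statistic), 0.18)
  })
})

test_that("extracted iModulon sets summarize membership, variance, and category", {
  sim <- generate_compendium(200, 12, 2, 4, noise_sd = 0.3,
                             replicate_rho = 0.9, seed = 61)
  xc <- center_to_reference(sim$compendium)
  dec <- run_ica(xc, 4, 6, seed = 2)
  ims <- extract_imodulons(xc, dec)
  expect_s3_class(ims, "imodulon_set")
  expect_identical(nrow(ims$summary), ncol(dec$M))
  expect_lte(sum(ims$summary$explained_variance), 1)
  for (m in ims$imodulons) {
    expect_setequal(m$member_genes,
                    names(m$gene_weights)[abs(m$gene_weights) > m$threshold])
  }
})
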