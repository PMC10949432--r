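make_meta <- function(ids, project = "p1",
                      condition = rep("c1", length(ids)),
                      reads = 2e6, fastqc = TRUE,
                      is_ref = condition == condition[1]) {
  data.frame(sample_id = ids, project = project, condition = condition,
             replicate_index = seq_along(ids), is_reference = is_ref,
             mapped_reads = reads, fastqc_pass = fastqc,
             stringsAsFactors = FALSE)
}

test_that("read-count exclusion applies strictly below 500,000 mapped reads", {
  set.seed(1)
  vals <- matrix(rnorm(40), 10, 4,
                 dimnames = list(sprintf("g%02d", 1:10),
                                 c("a1", "a2", "b1", "b2")))
  md <- make_meta(colnames(vals), condition = c("c1", "c1", "c2", "c2"),
                  reads = c(499999, 2e6, 500000, 2e6))
  res <- exclude_failing_samples(compendium(vals, md))
  excl <- res$report$excluded_samples
  # a1 fails the read cutoff; a2 is then left without a replicate partner
  expect_setequal(excl$sample_id, c("a1", "a2"))
  expect_identical(excl$reason[excl$sample_id == "a1"], "low_reads")
  expect_identical(excl$reason[excl$sample_id == "a2"], "no_replicate")
  expect_setequal(colnames(res$compendium$values), c("b1", "b2"))

  # all passing: identity, empty report
  md2 <- make_meta(colnames(vals), condition = c("c1", "c1", "c2", "c2"))
  res2 <- exclude_failing_samples(compendium(vals, md2))
  expect_identical(res2$compendium$values, vals)
  expect_identical(nrow(res2$report$excluded_samples), 0L)
})

test_that("fastqc failures and missing metadata are excluded with their reasons", {
  set.seed(2)
  vals <- matrix(rnorm(60), 10, 6,
                 dimnames = list(sprintf("g%02d", 1:10),
                                 sprintf("s%d", 1:6)))
  md <- make_meta(colnames(vals),
                  condition = rep(c("c1", "c2", "c3"), each = 2),
                  fastqc = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE))
  md$condition[6] <- NA
  res <- exclude_failing_samples(compendium(vals, md))
  excl <- res$report$excluded_samples
  expect_identical(excl$reason[excl$sample_id == "s3"], "fastqc_fail")
  expect_identical(excl$reason[excl$sample_id == "s6"], "no_metadata")
})

test_that("groups with any low pairwise correlation collapse to their mean", {
  x <- toy_qc_compendium()
  res <- replicate_correlation_filter(x, threshold = 0.80)
  avg <- res$report$averaged_groups
  expect_length(avg, 1)
  expect_identical(avg[[1]]$condition, "c2")
  expect_true(any(avg[[1]]$pairwise_r < 0.80))
  # averaged column equals the brute-force elementwise mean
  manual <- (x$values[, "c2_r1"] + x$values[, "c2_r2"]) / 2
  expect_equal(unname(res$compendium$values[, "c2_avg"]), unname(manual))
  # consistent groups pass unchanged
  expect_identical(res$compendium$values[, "c1_r1"], x$values[, "c1_r1"])
  expect_identical(res$compendium$values[, "c3_r2"], x$values[, "c3_r2"])
  # identical columns: r = 1 everywhere, nothing averaged
  dup <- x
  dup$values[, "c2_r2"] <- dup$values[, "c2_r1"]
  expect_length(replicate_correlation_filter(dup)$report$averaged_groups, 0)
})

test_that("averaged-group counts are non-decreasing across the threshold sweep", {
  sim <- generate_compendium(300, 12, 3, 4, noise_sd = 1.2,
                             replicate_rho = 0.7, seed = 31)
  sweep <- qc_threshold_sweep(sim$compendium,
                              thresholds = c(0.80, 0.85, 0.90, 0.95))
  expect_true(all(diff(sweep$n_averaged_groups) >= 0))
})

test_that("high-fidelity replicates are almost never averaged at the working threshold", {
  # with rho = 0.95 the expected within-group r sits far above 0.80, but
  # the low-rank signal keeps a heavy lower tail: conditions whose module
  # activities happen to be weak can still dip below the threshold, so the
  # assertable property is a low rate, not strict zero
  total <- 0
  for (s in 1:5) {
    sim <- generate_compendium(1000, 10, 3, 8, noise_sd = 0.3,
                               replicate_rho = 0.95, seed = 40 + s)
    total <- total +
      length(replicate_correlation_filter(sim$compendium,
                                          0.80)$report$averaged_groups)
  }
  expect_lte(total / 50, 0.10)   # <= 10% of the 50 condition groups
})

test_that("zero-variance samples abort correlation filtering by name", {
  x <- toy_qc_compendium()
  x$values[, "c1_r2"] <- 3
  expect_error(replicate_correlation_filter(x), "c1_r2")
})

test_that("reference centering zeroes the reference group and is idempotent", {
  x <- toy_qc_compendium()
  centered <- center_to_reference(x)
  ref_cols <- x$metadata$sample_id[x$metadata$is_reference]
  expect_equal(max(abs(rowMeans(centered$values[, ref_cols]))), 0)
  # manual subtraction on a two-project toy
  set.seed(3)
  vals <- matrix(rnorm(40), 5, 8,
                 dimnames = list(sprintf("g%d", 1:5), sprintf("s%d", 1:8)))
  md <- data.frame(sample_id = colnames(vals),
                   project = rep(c("p1", "p2"), each = 4),
                   condition = rep(c("c1", "c1", "c2", "c2",
                                     "c3", "c3", "c4", "c4")),
                   replicate_index = rep(1:2, 4),
                   is_reference = rep(c(TRUE, TRUE, FALSE, FALSE), 2),
                   mapped_reads = 2e6, fastqc_pass = TRUE,
                   stringsAsFactors = FALSE)
  two <- compendium(vals, md)
  cen <- center_to_reference(two)
  expect_equal(cen$values[, "s3"],
               vals[, "s3"] - rowMeans(vals[, c("s1", "s2")]))
  expect_equal(cen$values[, "s7"],
               vals[, "s7"] - rowMeans(vals[, c("s5", "s6")]))
  # idempotence
  expect_equal(center_to_reference(cen)$values, cen$values)
  # missing reference errors with the project name
  md2 <- md
  md2$is_reference <- FALSE
  expect_error(center_to_reference(compendium(vals, md2)), "p1")
})

test_that("QC operations preserve gene order and never invent samples", {
  x <- toy_qc_compendium()
  r1 <- exclude_failing_samples(x)
  r2 <- replicate_correlation_filter(r1$compendium)
  r3 <- center_to_reference(r2$compendium)
  expect_identical(rownames(r3$values), rownames(x$values))
  allowed <- c(x$metadata$sample_id,
               paste0(unique(x$metadata$condition), "_avg"))
  expect_true(all(colnames(r3$values) %in% allowed))
})

test_that("the advisory outlier screen flags a deliberately alien sample", {
  sim <- generate_compendium(300, 6, 3, 3, noise_sd = 0.1,
                             replicate_rho = 0.95, seed = 51)
  x <- sim$compendium
  x$values[, 1] <- rnorm(nrow(x$values), sd = 3)  # unrelated profile
  rep <- sample_outlier_report(x, cut_height = 0.7)
  expect_true(colnames(x$values)[1] %in% rep$flagged)
})
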