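# Independent oracles used by the unit and acceptance tests.  These are
# deliberately naive (enumeration / direct arithmetic) and share no code
# with the implementation paths they check.

# Brute-force operon partition: decide joins pairwise, then rebuild the
# partition from the join decisions.
oracle_operon_partition <- function(genes, gap_threshold,
                                    require_same_strand = TRUE) {
  parts <- list()
  for (acc in unique(genes$accession)) {
    g <- genes[genes$accession == acc, ]
    g <- g[order(g$start, g$end), ]
    joins <- logical(max(nrow(g) - 1, 0))
    for (i in seq_along(joins)) {
      gap <- max(g$start[i + 1] - g$end[i] - 1, 0)
      joins[i] <- gap <= gap_threshold &&
        (!require_same_strand || g$strand[i + 1] == g$strand[i])
    }
    op <- cumsum(c(TRUE, !joins))
    parts <- c(parts, unname(split(g$gene_id, op)))
  }
  parts
}

# Canonical form of a gene partition for comparison.
canonical_partition <- function(parts) {
  parts <- lapply(parts, sort)
  parts[order(vapply(parts, `[`, "", 1))]
}

# Exhaustive PSSM window scoring via substring arithmetic.
oracle_best_window <- function(sequence, log_odds, reverse = TRUE) {
  w <- ncol(log_odds)
  score_one <- function(s) {
    best <- -Inf; best_off <- NA
    for (o in seq_len(nchar(s) - w + 1)) {
      win <- strsplit(substr(s, o, o + w - 1), "")[[1]]
      sc <- 0
      ok <- TRUE
      for (i in seq_len(w)) {
        row <- match(win[i], c("A", "C", "G", "T"))
        if (is.na(row)) { ok <- FALSE; break }
        sc <- sc + log_odds[row, i]
      }
      if (ok && sc > best) { best <- sc; best_off <- o - 1 }
    }
    list(score = unname(best), offset = best_off)
  }
  fw <- score_one(sequence)
  if (!reverse) return(fw)
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", sequence), "")[[1]]),
              collapse = "")
  rv <- score_one(rc)
  if (rv$score > fw$score)
    list(score = rv$score,
         offset = nchar(sequence) - w - rv$offset)
  else fw
}

# Hypergeometric upper-tail P(overlap >= k) by direct summation of the
# probability mass function.
oracle_hyper_tail <- function(k, regulon_size, universe, draw) {
  sum(vapply(k:min(regulon_size, draw), function(i) {
    choose(regulon_size, i) * choose(universe - regulon_size, draw - i) /
      choose(universe, draw)
  }, 1.0))
}

# AUC as the fraction of concordant (positive, negative) score pairs,
# ties counting one half.
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  conc <- 0
  for (p in pos) for (n in neg)
    conc <- conc + (p > n) + 0.5 * (p == n)
  conc / (length(pos) * length(neg))
}

# Small positive-control PWM: near-deterministic, aperiodic 10-mer (a
# periodic consensus would let sampling errors shift the best window by
# one period).
toy_pwm <- function(consensus = "TGACGTTAGC", p = 0.97) {
  bases <- strsplit(consensus, "")[[1]]
  pwm <- matrix((1 - p) / 3, 4, length(bases),
                dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(bases)) pwm[bases[j], j] <- p
  pwm
}

# Hand-built six-sample compendium: two projects x one condition each is
# too small for centering tests, so: one project, three conditions of two
# replicates, with cond2's second replicate anti-correlated.
toy_qc_compendium <- function(n_genes = 60, seed = 99) {
  withr::with_seed(seed, {
    base <- matrix(rnorm(n_genes * 3), n_genes, 3)
    vals <- cbind(
      base[, 1], base[, 1] + rnorm(n_genes, sd = 0.05),
      base[, 2], -base[, 2] + rnorm(n_genes, sd = 0.05),
      base[, 3], base[, 3] + rnorm(n_genes, sd = 0.05)
    )
    dimnames(vals) <- list(sprintf("g%03d", 1:n_genes),
                           c("c1_r1", "c1_r2", "c2_r1", "c2_r2",
                             "c3_r1", "c3_r2"))
    md <- data.frame(
      sample_id = colnames(vals),
      project = "proj01",
      condition = rep(c("c1", "c2", "c3"), each = 2),
      replicate_index = rep(1:2, 3),
      is_reference = rep(c(TRUE, FALSE, FALSE), each = 2),
      mapped_reads = 2e6,
      fastqc_pass = TRUE,
      stringsAsFactors = FALSE
    )
    compendium(vals, md)
  })
}

# Synthetic planted-motif classification bundle shared by classifier tests
# and the acceptance suite.
planted_motif_bundle <- function(n_genes = 120, n_operons = 60,
                                 n_positive = 15, seed = 11) {
  pwm <- toy_pwm()
  gen <- generate_genome(n_genes, n_operons, gap_within = 50,
                         gap_between = 600, seed = seed,
                         motif_pwm = pwm,
                         motif_operons = seq_len(n_positive))
  om <- cluster_operons(gen$genes, gap_threshold = 500)
  sites <- withr::with_seed(seed + 1,
                            replicate(30, imodulome:::sample_site(pwm)))
  pssm <- build_pssm(sites, c(A = .25, C = .25, G = .25, T = .25))
  scores <- score_operon_promoters(om, gen$promoters, pssm)
  gm <- gene_motif_scores(scores, om)
  pos_ops <- sprintf("operon_%03d", seq_len(n_positive))
  labels <- setNames(
    as.integer(gen$operon_truth$operon_id[
      match(gm$gene_id, gen$operon_truth$gene_id)] %in% pos_ops),
    gm$gene_id)
  features <- matrix(gm$best_score, ncol = 1,
                     dimnames = list(gm$gene_id, "best_score"))
  list(genome = gen, operon_map = om, pssm = pssm, scores = scores,
       features = features, labels = labels)
}
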