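DNA_BASES <- c("A", "C", "G", "T")

#' Build a position-specific scoring matrix from aligned binding sites
#'
#' Counts nucleotide frequencies at each position of the aligned sites
#' (plus a pseudocount), normalizes them to probabilities, and scores them
#' against the mononucleotide background frequency of `background_source`,
#' giving log-odds in bits: `log2(p / background)`.
#'
#' @param aligned_sites character vector of >= 2 equal-length ACGT
#'   sequences (ambiguity codes rejected).
#' @param background_source either sequences whose mononucleotide
#'   frequencies define the background, or an explicit named numeric vector
#'   c(A=,C=,G=,T=) summing to 1.
#' @param pseudocount added to every base count per position (default 0.5).
#' @return a `pssm`: list(width, probabilities (4 x width), background,
#'   log_odds (bits), pseudocount, n_sites).
#' @export
build_pssm <- function(aligned_sites, background_source, pseudocount = 0.5) {
  if (length(aligned_sites) < 2)
    stop("need >= 2 aligned sites", call. = FALSE)
  aligned_sites <- toupper(aligned_sites)
  w <- unique(nchar(aligned_sites))
  if (length(w) != 1)
    stop("aligned sites must all have the same length", call. = FALSE)
  if (w == 0) stop("empty sites", call. = FALSE)
  chars <- strsplit(aligned_sites, "")
  if (!all(unlist(chars) %in% DNA_BASES))
    stop("sites may contain only A, C, G, T", call. = FALSE)
  check_scalar(pseudocount, "pseudocount", lower = 0)

  counts <- matrix(0, 4, w, dimnames = list(DNA_BASES, NULL))
  for (s in chars)
    counts[cbind(match(s, DNA_BASES), seq_len(w))] <-
      counts[cbind(match(s, DNA_BASES), seq_len(w))] + 1
  probs <- sweep(counts + pseudocount, 2,
                 colSums(counts) + 4 * pseudocount, "/")

  background <- background_frequencies(background_source)
  observed <- rowSums(probs) > 0
  if (any(observed & background == 0))
    stop("zero background frequency for an observed base: ",
         paste(DNA_BASES[observed & background == 0], collapse = ", "),
         call. = FALSE)
  log_odds <- log2(sweep(probs, 1, background, "/"))
  structure(list(width = w, probabilities = probs, background = background,
                 log_odds = log_odds, pseudocount = pseudocount,
                 n_sites = length(aligned_sites)),
            class = "pssm")
}

background_frequencies <- function(background_source) {
  if (is.numeric(background_source)) {
    if (!all(DNA_BASES %in% names(background_source)))
      stop("explicit background must be named A,C,G,T", call. = FALSE)
    bg <- background_source[DNA_BASES]
    if (abs(sum(bg) - 1) > 1e-6)
      stop("background frequencies must sum to 1", call. = FALSE)
    return(bg)
  }
  chars <- unlist(strsplit(toupper(background_source), ""))
  chars <- chars[chars %in% DNA_BASES]
  if (!length(chars))
    stop("background source contains no ACGT characters", call. = FALSE)
  freq <- table(factor(chars, levels = DNA_BASES)) / length(chars)
  setNames(as.numeric(freq), DNA_BASES)
}

#' @export
print.pssm <- function(x, ...) {
  consensus <- paste(DNA_BASES[apply(x$probabilities, 2, which.max)],
                     collapse = "")
  cat(sprintf("<pssm> width %d, %d sites, consensus %s\n",
              x$width, x$n_sites, consensus))
  invisible(x)
}

#' Consensus sequence of a PSSM
#' @param pssm a `pssm`.
#' @return character string of most probable bases.
#' @export
pssm_consensus <- function(pssm) {
  paste(DNA_BASES[apply(pssm$probabilities, 2, which.max)], collapse = "")
}

reverse_complement <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]),
          collapse = "")
  }, "", USE.NAMES = FALSE)
}

# Score every width-w window of an integer-encoded sequence; windows
# containing non-ACGT characters get NA.
scan_windows <- function(idx, log_odds) {
  w <- ncol(log_odds)
  n_win <- length(idx) - w + 1L
  if (n_win < 1) return(numeric(0))
  scores <- numeric(n_win)
  for (i in seq_len(w)) {
    b <- idx[i:(i + n_win - 1L)]
    scores <- scores + ifelse(is.na(b), NA, log_odds[cbind(b, i)])
  }
  scores
}

#' Scan a sequence with a PSSM and return the best-scoring window
#'
#' Scores every window of the motif width at step 1 on the forward strand
#' and, by default, on the reverse complement, returning the maximum score,
#' its 0-based offset (window start in the coordinates of the input
#' sequence on either strand), and the strand.  Ties are broken forward
#' strand first, then smallest offset.
#'
#' @param sequence a single ACGT character string (length >= motif width).
#' @param pssm a `pssm`.
#' @param scan_reverse_complement also scan the reverse complement
#'   (default TRUE).
#' @param ambiguous what to do with non-ACGT characters: "skip" windows
#'   containing them (default) or "error".
#' @return list(best_score, best_offset, strand).
#' @export
motif_search <- function(sequence, pssm, scan_reverse_complement = TRUE,
                         ambiguous = c("skip", "error")) {
  stopifnot(inherits(pssm, "pssm"), is.character(sequence),
            length(sequence) == 1)
  ambiguous <- match.arg(ambiguous)
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  w <- pssm$width
  if (n < w)
    stop("sequence shorter than motif width", call. = FALSE)
  idx <- match(strsplit(sequence, "")[[1]], DNA_BASES)
  if (anyNA(idx) && ambiguous == "error")
    stop("sequence contains non-ACGT characters", call. = FALSE)

  fw <- scan_windows(idx, pssm$log_odds)
  candidates <- data.frame(score = fw, offset = seq_along(fw) - 1L,
                           strand = "+", stringsAsFactors = FALSE)
  if (scan_reverse_complement) {
    idx_rc <- rev(5L - idx)  # A<->T, C<->G on the reversed sequence
    rc <- scan_windows(idx_rc, pssm$log_odds)
    # window j (0-based) on the reverse strand starts at n - w - j forward
    candidates <- rbind(candidates,
                        data.frame(score = rc,
                                   offset = n - w - (seq_along(rc) - 1L),
                                   strand = "-", stringsAsFactors = FALSE))
  }
  candidates <- candidates[!is.na(candidates$score), , drop = FALSE]
  if (!nrow(candidates))
    stop("no scorable window (all windows contain non-ACGT characters)",
         call. = FALSE)
  # forward strand wins ties, then smaller offset
  candidates <- candidates[order(-candidates$score,
                                 candidates$strand != "+",
                                 candidates$offset), , drop = FALSE]
  list(best_score = candidates$score[1],
       best_offset = candidates$offset[1],
       strand = candidates$strand[1])
}

#' Score operon promoters with a PSSM
#'
#' Runs [motif_search()] on the upstream promoter sequence of every operon
#' and reports the best window score per operon; genes inherit their
#' operon's score via [gene_motif_scores()].  Operons without a promoter
#' sequence are flagged with a warning and excluded.
#'
#' @param operon_map an `operon_map` from [cluster_operons()].
#' @param promoters named character vector of promoter sequences keyed by
#'   operon id or by the operon's lead gene id (the first gene in genomic
#'   order).
#' @param pssm a `pssm`.
#' @param scan_reverse_complement passed to [motif_search()].
#' @return data.frame (operon_id, best_score, best_offset, strand_scanned).
#' @export
score_operon_promoters <- function(operon_map, promoters, pssm,
                                   scan_reverse_complement = TRUE) {
  stopifnot(inherits(operon_map, "operon_map"))
  tab <- operon_map$table
  operons <- unique(tab$operon_id)
  # promoter lookup: operon id directly, else the operon's lead gene
  lead <- vapply(operons, function(o) {
    g <- tab[tab$operon_id == o, ]
    g$gene_id[which.min(g$start)]
  }, "")
  key <- ifelse(operons %in% names(promoters), operons,
                ifelse(lead %in% names(promoters), lead, NA))
  if (anyNA(key))
    warning("no promoter sequence for operon(s): ",
            paste(operons[is.na(key)], collapse = ", "), " -- excluded",
            call. = FALSE)
  found <- !is.na(key)
  rows <- lapply(which(found), function(i) {
    o <- operons[i]
    hit <- motif_search(promoters[[key[i]]], pssm,
                        scan_reverse_complement = scan_reverse_complement)
    data.frame(operon_id = o, best_score = hit$best_score,
               best_offset = hit$best_offset,
               strand_scanned = hit$strand, stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(operon_id = character(), best_score = numeric(),
                      best_offset = integer(),
                      strand_scanned = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Expand operon motif scores to genes
#'
#' @param score_table output of [score_operon_promoters()].
#' @param operon_map an `operon_map`.
#' @return data.frame (gene_id, operon_id, best_score).
#' @export
gene_motif_scores <- function(score_table, operon_map) {
  stopifnot(inherits(operon_map, "operon_map"))
  tab <- operon_map$table[operon_map$table$operon_id %in%
                            score_table$operon_id, ]
  idx <- match(tab$operon_id, score_table$operon_id)
  data.frame(gene_id = tab$gene_id, operon_id = tab$operon_id,
             best_score = score_table$best_score[idx],
             stringsAsFactors = FALSE)
}

#' Read binding sites from FASTA or plain text
#'
#' FASTA input (leading `>`) is parsed with Biostrings; otherwise one site
#' per line is assumed.  Sequences are uppercased.
#'
#' @param path input file.
#' @return character vector of sites.
#' @export
read_sites <- function(path) {
  first <- readLines(path, n = 1)
  if (length(first) && startsWith(first, ">")) {
    seqs <- as.character(Biostrings::readDNAStringSet(path))
  } else {
    seqs <- readLines(path)
    seqs <- seqs[nzchar(seqs)]
  }
  toupper(unname(seqs))
}

#' Read / write promoter sequences as FASTA
#'
#' Lowercase bases are uppercased on read.
#'
#' @param path FASTA file path.
#' @return [read_promoters()]: named character vector.
#' @export
read_promoters <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(seqs)), names(seqs))
}

#' @rdname read_promoters
#' @param promoters named character vector of sequences.
#' @export
write_promoters <- function(promoters, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(unlist(promoters)), path)
  invisible(promoters)
}

#' Serialize a PSSM
#'
#' `write_pssm_json()` writes the full object as JSON;
#' `write_pssm_meme()` writes MEME minimal motif format.
#'
#' @param pssm a `pssm`.
#' @param path output path.
#' @param name motif name used in the MEME header.
#' @return the pssm, invisibly.
#' @export
write_pssm_json <- function(pssm, path) {
  stopifnot(inherits(pssm, "pssm"))
  obj <- list(width = pssm$width,
              probabilities = as.data.frame(t(pssm$probabilities)),
              background = as.list(setNames(as.numeric(pssm$background),
                                            DNA_BASES)),
              log_odds = as.data.frame(t(pssm$log_odds)),
              pseudocount = pssm$pseudocount, n_sites = pssm$n_sites)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(pssm)
}

#' @rdname write_pssm_json
#' @export
write_pssm_meme <- function(pssm, path, name = "motif_1") {
  stopifnot(inherits(pssm, "pssm"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "Background letter frequencies",
               paste(sprintf("%s %.5f", DNA_BASES,
                             as.numeric(pssm$background)),
                     collapse = " "), "",
               sprintf("MOTIF %s", name),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                       pssm$width, pssm$n_sites)), con)
  writeLines(apply(pssm$probabilities, 2, function(p)
    paste(sprintf("%.6f", p), collapse = " ")), con)
  invisible(pssm)
}

#' Read a PSSM written by [write_pssm_json()]
#' @param path JSON file path.
#' @return a `pssm`.
#' @export
read_pssm_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  probs <- t(as.matrix(obj$probabilities))
  dimnames(probs) <- list(DNA_BASES, NULL)
  lo <- t(as.matrix(obj$log_odds))
  dimnames(lo) <- list(DNA_BASES, NULL)
  structure(list(width = obj$width, probabilities = probs,
                 background = setNames(unlist(obj$background), DNA_BASES),
                 log_odds = lo, pseudocount = obj$pseudocount,
                 n_sites = obj$n_sites),
            class = "pssm")
}
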