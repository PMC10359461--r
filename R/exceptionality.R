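# Word exceptionality under the maximal Markov model of order m = k - 2.
#
# For a word W of length k, write W- for its (k-1)-prefix, -W for its (k-1)
# suffix and -W- for its (k-2)-length middle. With overlapping occurrence
# counts N() taken over the scored sequence, the maximal-model estimator is
#
#   E_hat = N(W-) N(-W) / N(-W-)
#   V_hat = E_hat (1 - N(W-)/N(-W-)) (1 - N(-W)/N(-W-))
#   Z     = (N(W) - E_hat) / sqrt(V_hat)
#
# Negative Z indicates avoidance (fewer occurrences than expected given the
# counts of all sub-words up to length k - 1); positive Z indicates
# over-representation. When a word is never observed and never expected
# (N = 0, E_hat = 0) its score is defined as zero. Other zero-variance cases
# are flagged degenerate and excluded from group summaries.

as_count_table <- function(x, k_needed) {
  if (inherits(x, "kmer_count_table")) {
    if (x$k_max < k_needed)
      stop(sprintf("count table k_max %d < required word length %d",
                   x$k_max, k_needed), call. = FALSE)
    x
  } else {
    build_count_table(x, k_needed)
  }
}

#' Expected word count under the maximal Markov model
#'
#' @param word Unambiguous DNA word of length k >= 3 (the model order
#'   m = k - 2 must be at least 1).
#' @param counts A `kmer_count_table` covering lengths up to k, or a sequence.
#' @return Expected overlapping count (0 when the middle word is unobserved).
#' @examples
#' expected_count_maximal("AAT", build_count_table("AATAAT", 3))  # 1.0
#' @export
expected_count_maximal <- function(word, counts) {
  assert_dna_word(word)
  k <- nchar(word)
  if (k < 3L)
    stop("unsupported order: the maximal model requires word length k >= 3 (m = k - 2 >= 1)",
         call. = FALSE)
  counts <- as_count_table(counts, k)
  a <- count_word(counts, substr(word, 1L, k - 1L))
  b <- count_word(counts, substr(word, 2L, k))
  cc <- count_word(counts, substr(word, 2L, k - 1L))
  if (cc == 0) return(0)
  a * b / cc
}

#' Variance of the word count under the maximal Markov model
#'
#' @inheritParams expected_count_maximal
#' @return Estimated variance (0 when the middle word is unobserved or either
#'   conditional frequency is 1).
#' @export
variance_maximal <- function(word, counts) {
  assert_dna_word(word)
  k <- nchar(word)
  if (k < 3L)
    stop("unsupported order: the maximal model requires word length k >= 3 (m = k - 2 >= 1)",
         call. = FALSE)
  counts <- as_count_table(counts, k)
  a <- count_word(counts, substr(word, 1L, k - 1L))
  b <- count_word(counts, substr(word, 2L, k))
  cc <- count_word(counts, substr(word, 2L, k - 1L))
  if (cc == 0) return(0)
  (a * b / cc) * (1 - a / cc) * (1 - b / cc)
}

#' Exceptionality Z-score for one word in one sequence
#'
#' @param x DNA sequence (character scalar) or a prebuilt `kmer_count_table`.
#' @param word Unambiguous DNA word of length k >= 3.
#' @return One-row data.frame with columns `word`, `observed`, `expected`,
#'   `variance`, `z`, `flag`. Flags: `"ok"`; `"zero_zero"` (never observed,
#'   never expected; z defined as 0); `"degenerate"` (zero variance with a
#'   non-trivial discrepancy; z is `NA` and the word is excluded from group
#'   aggregation).
#' @examples
#' z_score("AATAAT", "AAT")  # z = 2
#' @export
z_score <- function(x, word) {
  assert_dna_word(word)
  k <- nchar(word)
  if (k < 3L)
    stop("unsupported order: the maximal model requires word length k >= 3 (m = k - 2 >= 1)",
         call. = FALSE)
  counts <- as_count_table(x, k)
  N <- as.numeric(count_word(counts, word))
  E <- expected_count_maximal(word, counts)
  V <- variance_maximal(word, counts)
  if (V > 0) {
    z <- (N - E) / sqrt(V)
    flag <- "ok"
  } else if (N == 0 && E == 0) {
    z <- 0
    flag <- "zero_zero"
  } else {
    z <- NA_real_
    flag <- "degenerate"
  }
  data.frame(word = word, observed = N, expected = E, variance = V,
             z = z, flag = flag, stringsAsFactors = FALSE)
}

#' Exceptionality Z-scores for all 4^k words of one length
#'
#' Vectorised over the whole word space; identical to calling [z_score()] on
#' each word but far faster.
#'
#' @param x DNA sequence or `kmer_count_table`.
#' @param k Word length (>= 3).
#' @return data.frame with one row per word (lexicographic order), columns as
#'   in [z_score()].
#' @export
zscore_all_kmers <- function(x, k) {
  stopifnot(is.numeric(k), length(k) == 1L)
  k <- as.integer(k)
  if (k < 3L)
    stop("unsupported order: the maximal model requires word length k >= 3 (m = k - 2 >= 1)",
         call. = FALSE)
  counts <- as_count_table(x, k)
  words <- names(counts$counts[[k]])
  N <- as.numeric(counts$counts[[k]])
  a <- as.numeric(counts$counts[[k - 1L]][substr(words, 1L, k - 1L)])
  b <- as.numeric(counts$counts[[k - 1L]][substr(words, 2L, k)])
  cc <- if (k == 3L) {
    as.numeric(counts$counts[[1L]][substr(words, 2L, 2L)])
  } else {
    as.numeric(counts$counts[[k - 2L]][substr(words, 2L, k - 1L)])
  }
  E <- ifelse(cc == 0, 0, a * b / cc)
  V <- ifelse(cc == 0, 0, E * (1 - a / cc) * (1 - b / cc))
  z <- rep(NA_real_, length(words))
  flag <- rep("degenerate", length(words))
  ok <- V > 0
  z[ok] <- (N[ok] - E[ok]) / sqrt(V[ok])
  flag[ok] <- "ok"
  zz <- !ok & N == 0 & E == 0
  z[zz] <- 0
  flag[zz] <- "zero_zero"
  data.frame(word = words, observed = N, expected = E, variance = V,
             z = z, flag = flag, stringsAsFactors = FALSE)
}

#' Subsample gene sequences to a fixed total length
#'
#' Genes are drawn uniformly without replacement, concatenated, and truncated
#' to exactly `target_length` bases, mirroring fixed-length subsampling of a
#' pangenome component before scoring (so statistical power is comparable
#' across components of different sizes). Deterministic given `seed`.
#'
#' @param genes Character vector of gene sequences.
#' @param target_length Required output length in bases (must exceed the word
#'   lengths scored downstream; canonical choices 2500, 5000, 10000, 50000,
#'   100000).
#' @param seed Integer seed for the gene draw.
#' @return A single DNA string of exactly `target_length` bases, or
#'   `NA_character_` (with attribute `excluded = TRUE`) when the genes total
#'   less than `target_length` — the record is excluded, not an error.
#' @export
subsample_genes <- function(genes, target_length, seed) {
  stopifnot(is.character(genes), is.numeric(target_length), target_length > 0)
  total <- sum(nchar(genes))
  if (total < target_length)
    return(structure(NA_character_, excluded = TRUE))
  ord <- with_seed(seed, sample.int(length(genes)))
  lens <- cumsum(nchar(genes)[ord])
  take <- seq_len(which(lens >= target_length)[1L])
  substr(paste(genes[ord[take]], collapse = ""), 1L, target_length)
}

#' Median exceptionality score of a group of target words
#'
#' Each member word is scored with [z_score()]; the group summary is the exact
#' median of the member scores. Words flagged degenerate are excluded from the
#' median; `zero_zero` words enter as 0.
#'
#' @param x DNA sequence or `kmer_count_table`.
#' @param targets Character vector of unambiguous DNA words (all one length).
#' @param label Optional group label carried through to the result.
#' @return A `target_group_score`: list with `label`, `scores` (per-word
#'   data.frame), `median_z`, `n_scored`, and `flag` (`"ok"` or
#'   `"undefined"` for an empty or fully-degenerate group).
#' @export
score_target_group <- function(x, targets, label = NA_character_) {
  if (length(targets) == 0L) {
    return(structure(list(label = label, scores = NULL, median_z = NA_real_,
                          n_scored = 0L, flag = "undefined"),
                     class = "target_group_score"))
  }
  k <- unique(nchar(targets))
  if (length(k) != 1L)
    stop("all target words in a group must have the same length", call. = FALSE)
  counts <- as_count_table(x, k)
  scores <- do.call(rbind, lapply(targets, function(w) z_score(counts, w)))
  usable <- scores$z[!is.na(scores$z)]
  if (length(usable) == 0L) {
    return(structure(list(label = label, scores = scores, median_z = NA_real_,
                          n_scored = 0L, flag = "undefined"),
                     class = "target_group_score"))
  }
  structure(list(label = label, scores = scores,
                 median_z = stats::median(usable),
                 n_scored = length(usable), flag = "ok"),
            class = "target_group_score")
}

#' @export
print.target_group_score <- function(x, ...) {
  cat(sprintf("target_group_score '%s': %d scored, median z = %s [%s]\n",
              x$label, x$n_scored,
              if (is.na(x$median_z)) "NA" else format(x$median_z, digits = 4),
              x$flag))
  invisible(x)
}

# Deterministically combine seed components into one valid 32-bit seed.
mix_seed <- function(...) {
  s <- 0
  for (x in c(...)) s <- (s * 1000003 + as.numeric(x)) %% 2147483647
  as.integer(s)
}

# Run code under a temporary RNG seed, restoring global RNG state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
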