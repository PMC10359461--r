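# DNA alphabet primitives: reverse complement, palindromes, IUPAC expansion,
# and overlapping word counting. Every other module consumes these.

IUPAC_CODES <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

# Complement pairs over the full 15-letter degenerate alphabet.
IUPAC_FROM <- "ACGTRYSWKMBDHVN"
IUPAC_TO   <- "TGCAYRSWMKVHDBN"

assert_iupac <- function(x, arg = "motif") {
  if (length(x) != 1L || is.na(x) || !nzchar(x))
    stop(sprintf("'%s' must be a single non-empty string", arg), call. = FALSE)
  chars <- strsplit(x, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% names(IUPAC_CODES))
  if (length(bad))
    stop(sprintf("invalid IUPAC character '%s' at position %d in '%s'",
                 chars[bad[1L]], bad[1L], arg), call. = FALSE)
  invisible(x)
}

assert_dna_word <- function(x, arg = "word") {
  if (length(x) != 1L || is.na(x) || !nzchar(x))
    stop(sprintf("'%s' must be a single non-empty string", arg), call. = FALSE)
  chars <- strsplit(x, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% c("A", "C", "G", "T"))
  if (length(bad))
    stop(sprintf("invalid DNA character '%s' at position %d in '%s' (only A/C/G/T allowed)",
                 chars[bad[1L]], bad[1L], arg), call. = FALSE)
  invisible(x)
}

#' Reverse complement of a DNA word or degenerate IUPAC motif
#'
#' Complementation respects IUPAC degeneracy (R<->Y, K<->M, N<->N, ...), so the
#' operation is an involution over the full 15-letter alphabet.
#'
#' @param x Character vector of DNA words or IUPAC motifs (uppercase).
#' @return Character vector of the same length with each element reverse
#'   complemented.
#' @examples
#' reverse_complement("GAATTC")  # palindromic: returns itself
#' reverse_complement("ATNNAT")
#' @export
reverse_complement <- function(x) {
  vapply(x, function(m) {
    assert_iupac(m)
    comp <- chartr(IUPAC_FROM, IUPAC_TO, toupper(m))
    paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

#' Test whether an unambiguous DNA word is a palindrome
#'
#' A DNA palindrome equals its own reverse complement. No base is its own
#' complement, so odd-length words are never palindromic.
#'
#' @param word A single DNA word over A/C/G/T.
#' @return `TRUE` iff `word` equals its reverse complement.
#' @export
is_palindrome <- function(word) {
  assert_dna_word(word)
  word == reverse_complement(word)
}

#' Enumerate all DNA palindromes of a given even length
#'
#' A length-k palindrome is determined by its first k/2 bases, so there are
#' exactly 4^(k/2) of them (64 for k = 6).
#'
#' @param k Word length. Odd `k` yields an empty set (no odd DNA palindromes).
#' @return Character vector of palindromes in lexicographic order.
#' @examples
#' length(enumerate_palindromes(6))  # 64
#' enumerate_palindromes(2)
#' @export
enumerate_palindromes <- function(k) {
  stopifnot(is.numeric(k), length(k) == 1L, k >= 2)
  k <- as.integer(k)
  if (k %% 2L == 1L) return(character(0L))
  half <- k %/% 2L
  bases <- c("A", "C", "G", "T")
  grid <- do.call(expand.grid,
                  c(rep(list(bases), half), list(stringsAsFactors = FALSE)))
  halves <- sort(do.call(paste0, grid), method = "radix")
  paste0(halves, reverse_complement(halves))
}

#' Expand a degenerate IUPAC motif into its unambiguous k-mer targets
#'
#' Every degenerate position contributes its full set of bases; the expansion
#' size is the product of per-position degeneracies. Downstream analyses weight
#' all expansions equally.
#'
#' @param motif A single IUPAC motif string.
#' @return Character vector of unambiguous words, lexicographically sorted.
#' @examples
#' expand_iupac("GANTC")   # 4 words
#' expand_iupac("ATNNAT")  # 16 words
#' @export
expand_iupac <- function(motif) {
  assert_iupac(motif)
  pos <- strsplit(toupper(motif), "", fixed = TRUE)[[1L]]
  sets <- lapply(IUPAC_CODES[pos], function(s) strsplit(s, "", fixed = TRUE)[[1L]])
  grid <- do.call(expand.grid, c(unname(sets), list(stringsAsFactors = FALSE)))
  words <- do.call(paste0, grid)
  sort(unique(words), method = "radix")
}

#' Degeneracy of an IUPAC motif
#'
#' @param motif A single IUPAC motif string.
#' @return Integer product of per-position degeneracies (the expansion size).
#' @export
iupac_degeneracy <- function(motif) {
  assert_iupac(motif)
  pos <- strsplit(toupper(motif), "", fixed = TRUE)[[1L]]
  prod(nchar(IUPAC_CODES[pos]))
}

#' Count overlapping occurrences of a word in a sequence
#'
#' Counts every start position, overlaps included. Windows containing any
#' non-ACGT base never match. With `both_strands = TRUE` the count of the
#' reverse complement is added; this is intended for non-palindromic targets
#' (a palindrome would be counted twice).
#'
#' @param sequence DNA sequence (character scalar; may be empty or contain
#'   ambiguity codes, which simply never match).
#' @param word Unambiguous DNA word.
#' @param both_strands Add occurrences of the reverse complement (default
#'   `FALSE`: forward strand only, which is strand-symmetric for palindromes).
#' @return Non-negative integer count.
#' @examples
#' count_overlapping("AAAA", "AA")  # 3
#' @export
count_overlapping <- function(sequence, word, both_strands = FALSE) {
  assert_dna_word(word)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (is.na(sequence) || nchar(sequence) < nchar(word)) return(0L)
  subj <- Biostrings::DNAString(toupper(sequence))
  n <- Biostrings::countPattern(word, subj, fixed = TRUE)
  if (both_strands)
    n <- n + Biostrings::countPattern(reverse_complement(word), subj, fixed = TRUE)
  as.integer(n)
}

#' Build a table of overlapping k-mer counts for all lengths 1..k_max
#'
#' For each word length j, counts of all 4^j words are tabulated; windows
#' containing a non-ACGT base are skipped at every length, so with a clean
#' sequence the length-j counts sum to L - j + 1.
#'
#' @param sequence DNA sequence (character scalar).
#' @param k_max Largest word length to tabulate (>= 1).
#' @return A `kmer_count_table`: list with `L` (sequence length), `k_max`, and
#'   `counts`, a list of named integer vectors indexed by word length.
#' @export
build_count_table <- function(sequence, k_max) {
  stopifnot(is.character(sequence), length(sequence) == 1L, k_max >= 1)
  k_max <- as.integer(k_max)
  seq_u <- toupper(sequence)
  L <- nchar(seq_u)
  subj <- Biostrings::DNAString(if (L > 0L) seq_u else "")
  counts <- lapply(seq_len(k_max), function(j) {
    if (L < j) {
      v <- integer(4L^j)
      names(v) <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), j)
      v
    } else {
      Biostrings::oligonucleotideFrequency(subj, width = j)
    }
  })
  structure(list(L = L, k_max = k_max, counts = counts),
            class = "kmer_count_table")
}

#' @export
print.kmer_count_table <- function(x, ...) {
  cat(sprintf("kmer_count_table: L = %d, word lengths 1..%d\n", x$L, x$k_max))
  invisible(x)
}

#' Look up a word's overlapping count in a count table
#'
#' @param table A `kmer_count_table` from [build_count_table()].
#' @param word Unambiguous DNA word of length <= `k_max`.
#' @return Integer count.
#' @export
count_word <- function(table, word) {
  stopifnot(inherits(table, "kmer_count_table"))
  assert_dna_word(word)
  k <- nchar(word)
  if (k > table$k_max)
    stop(sprintf("word length %d exceeds table k_max %d", k, table$k_max),
         call. = FALSE)
  unname(table$counts[[k]][word])
}

# --- FASTA IO (thin wrappers; record ids preserved verbatim) ---

#' Read a DNA FASTA file into a named character vector
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_dna_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- names(x)
  out
}

#' Read a protein FASTA file into a named character vector
#' @param path Path to a FASTA file.
#' @return Named character vector of amino-acid sequences.
#' @export
read_protein_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  out <- as.character(x)
  names(out) <- names(x)
  out
}

#' Write named sequences to a FASTA file
#' @param sequences Named character vector.
#' @param path Output path.
#' @param type `"dna"` or `"protein"`.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, type = c("dna", "protein")) {
  type <- match.arg(type)
  set <- if (type == "dna") Biostrings::DNAStringSet(sequences)
         else Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
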