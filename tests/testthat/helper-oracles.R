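# Independent oracles, deliberately free of the package's counting and
# scoring machinery: plain substring scans and the direct formula.

naive_count <- function(s, w) {
  k <- nchar(w); L <- nchar(s)
  if (L < k) return(0L)
  sum(vapply(seq_len(L - k + 1L),
             function(i) substr(s, i, i + k - 1L) == w, logical(1L)))
}

# Brute-force maximal-model score from naive counts.
brute_evz <- function(s, w) {
  k <- nchar(w)
  N <- naive_count(s, w)
  a <- naive_count(s, substr(w, 1L, k - 1L))
  b <- naive_count(s, substr(w, 2L, k))
  cc <- naive_count(s, substr(w, 2L, k - 1L))
  E <- if (cc == 0) 0 else a * b / cc
  V <- if (cc == 0) 0 else E * (1 - a / cc) * (1 - b / cc)
  z <- if (V > 0) (N - E) / sqrt(V) else if (N == 0 && E == 0) 0 else NA_real_
  list(N = N, E = E, V = V, z = z)
}

random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_word <- function(k, seed) random_dna(k, seed)

# A small synthetic taxonomy + presence matrix pair for dictionary tests.
toy_taxonomy <- function() {
  data.frame(
    species = c("Sa", "Sb", "Sc", "Sd"),
    genus   = c("G1", "G1", "G2", "G3"),
    family  = c("F1", "F1", "F1", "F2"),
    order   = c("O1", "O1", "O1", "O2"),
    class   = c("C1", "C1", "C1", "C2"),
    phylum  = c("P1", "P1", "P1", "P2"),
    kingdom = "Bacteria", stringsAsFactors = FALSE)
}
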