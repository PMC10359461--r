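# Detection of Type II restriction-modification systems in ordered proteomes.
#
# Candidate MTases and REases are identified by global-alignment percent
# identity to a target-annotated reference enzyme database (REBASE-like:
# enzyme class, protein sequence, recognition motif, evidence tier). A system
# call requires an MTase and a REase with the same normalised target within 4
# genes of each other (at most 3 intermediate genes). MTases with no cognate
# REase in that window are orphans. Only Type II systems with separate REase
# and MTase enzymes are handled; fused (Type IIG-style) entries in the
# reference are rejected with a warning.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

assert_protein <- function(x, arg = "protein") {
  if (length(x) != 1L || is.na(x) || !nzchar(x))
    stop(sprintf("'%s' must be a single non-empty amino-acid string", arg),
         call. = FALSE)
  chars <- strsplit(x, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% c(AA20, "X"))
  if (length(bad))
    stop(sprintf("invalid amino-acid character '%s' at position %d in '%s'",
                 chars[bad[1L]], bad[1L], arg), call. = FALSE)
  invisible(x)
}

#' Global-alignment percent identity between two proteins
#'
#' Needleman-Wunsch global alignment with BLOSUM62 and affine gap penalties
#' (open 10, extend 0.5). Identity is 100 * matches / alignment columns, with
#' gap columns in the denominator; `X` positions never count as matches.
#'
#' @param p1,p2 Amino-acid sequences (20-letter alphabet, `X` tolerated).
#' @return Percent identity in [0, 100]; symmetric in its arguments.
#' @export
percent_identity <- function(p1, p2) {
  assert_protein(p1, "p1")
  assert_protein(p2, "p2")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(p1), Biostrings::AAString(p2),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
  a <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  b <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  matches <- sum(a == b & a != "-" & a != "X")
  100 * matches / length(a)
}

#' Canonical form of a recognition motif
#'
#' Uppercases the motif and collapses it with its reverse complement to the
#' lexicographically smaller of the pair, so that the two strand
#' representations of one target compare equal.
#'
#' @param motif IUPAC motif (character vector).
#' @return Normalised motif(s).
#' @export
normalise_motif <- function(motif) {
  vapply(motif, function(m) {
    m <- toupper(m)
    rc <- reverse_complement(m)
    if (rc < m) rc else m
  }, character(1L), USE.NAMES = FALSE)
}

MTASE_IDENTITY_MIN <- 55
REASE_IDENTITY_MIN <- 50

identity_threshold <- function(class) {
  ifelse(class == "MTase", MTASE_IDENTITY_MIN, REASE_IDENTITY_MIN)
}

filter_db_tier <- function(db, tier = c("all", "nonputative", "gold")) {
  tier <- match.arg(tier)
  keep <- switch(tier,
                 gold       = db$tier == "gold",
                 nonputative = db$tier %in% c("gold", "nonputative"),
                 all        = rep(TRUE, nrow(db)))
  db[keep, , drop = FALSE]
}

validate_enzyme_db <- function(db) {
  need <- c("id", "class", "sequence", "motif", "tier")
  miss <- setdiff(need, names(db))
  if (length(miss))
    stop("enzyme db lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  fused <- !db$class %in% c("MTase", "REase")
  if (any(fused)) {
    warning(sprintf("dropping %d reference enzymes with unsupported class (%s): only Type II systems with separate MTase and REase are handled",
                    sum(fused), paste(unique(db$class[fused]), collapse = ", ")),
            call. = FALSE)
    db <- db[!fused, , drop = FALSE]
  }
  invisible(db)
}

validate_proteome <- function(proteome) {
  need <- c("genome_id", "replicon_id", "ordinal", "protein_id", "sequence")
  miss <- setdiff(need, names(proteome))
  if (length(miss))
    stop("proteome lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  dup <- duplicated(proteome[, c("genome_id", "replicon_id", "ordinal")])
  if (any(dup))
    stop("ordinal positions must be unique within a replicon", call. = FALSE)
  invisible(proteome)
}

#' Find reference-enzyme hits in an ordered proteome
#'
#' Each gene is compared to every reference enzyme of each class passing the
#' stringency tier; the best-identity enzyme per class is kept if it meets the
#' inclusive class threshold (>= 55% for MTases, >= 50% for REases). Ties are
#' broken by the lexicographically smallest enzyme id.
#'
#' @param proteome data.frame with columns `genome_id`, `replicon_id`,
#'   `ordinal` (gene order along the replicon), `protein_id`, `sequence`.
#' @param db Reference enzymes: data.frame with columns `id`, `class`
#'   (`"MTase"`/`"REase"`), `sequence`, `motif` (IUPAC), `tier`
#'   (`"gold"`/`"nonputative"`/`"putative"`).
#' @param tier Stringency: `"gold"` (experimentally characterised only),
#'   `"nonputative"` (gold + biochemically known), or `"all"` (default).
#' @return data.frame of hits: proteome columns plus `class`, `enzyme_id`,
#'   `identity`, `motif`, `motif_norm`.
#' @export
find_enzyme_hits <- function(proteome, db, tier = "all") {
  validate_proteome(proteome)
  db <- validate_enzyme_db(db)
  db <- filter_db_tier(db, tier)
  empty <- data.frame(genome_id = character(), replicon_id = character(),
                      ordinal = integer(), protein_id = character(),
                      class = character(), enzyme_id = character(),
                      identity = numeric(), motif = character(),
                      motif_norm = character(), stringsAsFactors = FALSE)
  if (nrow(db) == 0L) {
    warning("empty reference database after tier filtering; no hits possible",
            call. = FALSE)
    return(empty)
  }
  rows <- vector("list", nrow(proteome) * 2L)
  ri <- 0L
  for (g in seq_len(nrow(proteome))) {
    pid <- vapply(db$sequence, function(s)
      percent_identity(proteome$sequence[g], s), numeric(1L), USE.NAMES = FALSE)
    for (cls in c("MTase", "REase")) {
      idx <- which(db$class == cls & pid >= identity_threshold(cls))
      if (!length(idx)) next
      best <- idx[order(-pid[idx], db$id[idx])][1L]
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        genome_id = proteome$genome_id[g], replicon_id = proteome$replicon_id[g],
        ordinal = proteome$ordinal[g], protein_id = proteome$protein_id[g],
        class = cls, enzyme_id = db$id[best], identity = pid[best],
        motif = toupper(db$motif[best]),
        motif_norm = normalise_motif(db$motif[best]),
        stringsAsFactors = FALSE)
    }
  }
  if (ri == 0L) return(empty)
  do.call(rbind, rows[seq_len(ri)])
}

#' Pair MTase and REase hits into Type II R-M system calls
#'
#' Every (MTase hit, REase hit) pair on the same replicon with identical
#' normalised motifs and ordinal distance <= 4 (at most 3 intermediate genes)
#' yields one call. One enzyme may participate in several calls (overlapping
#' systems are allowed).
#'
#' @param hits Output of [find_enzyme_hits()].
#' @param max_gene_distance Maximum |ordinal difference| (default 4).
#' @return data.frame of calls: `genome_id`, `replicon_id`, `mtase_protein`,
#'   `rease_protein`, `mtase_ordinal`, `rease_ordinal`, `n_intermediate`,
#'   `motif` (normalised).
#' @export
call_rm_systems <- function(hits, max_gene_distance = 4L) {
  empty <- data.frame(genome_id = character(), replicon_id = character(),
                      mtase_protein = character(), rease_protein = character(),
                      mtase_ordinal = integer(), rease_ordinal = integer(),
                      n_intermediate = integer(), motif = character(),
                      stringsAsFactors = FALSE)
  if (is.null(hits) || nrow(hits) == 0L) return(empty)
  mt <- hits[hits$class == "MTase", , drop = FALSE]
  re <- hits[hits$class == "REase", , drop = FALSE]
  if (nrow(mt) == 0L || nrow(re) == 0L) return(empty)
  pairs <- merge(mt, re,
                 by.x = c("genome_id", "replicon_id", "motif_norm"),
                 by.y = c("genome_id", "replicon_id", "motif_norm"),
                 suffixes = c(".m", ".r"))
  if (nrow(pairs) == 0L) return(empty)
  d <- abs(pairs$ordinal.m - pairs$ordinal.r)
  pairs <- pairs[d <= max_gene_distance & d > 0L, , drop = FALSE]
  if (nrow(pairs) == 0L) return(empty)
  out <- data.frame(
    genome_id = pairs$genome_id, replicon_id = pairs$replicon_id,
    mtase_protein = pairs$protein_id.m, rease_protein = pairs$protein_id.r,
    mtase_ordinal = pairs$ordinal.m, rease_ordinal = pairs$ordinal.r,
    n_intermediate = abs(pairs$ordinal.m - pairs$ordinal.r) - 1L,
    motif = pairs$motif_norm, stringsAsFactors = FALSE)
  out[order(out$genome_id, out$replicon_id, out$mtase_ordinal, out$rease_ordinal), ,
      drop = FALSE]
}

#' Unique R-M targets recognised in a genome
#'
#' Overlapping systems recognising the same motif are counted once: the set of
#' distinct normalised motifs across a genome's calls.
#'
#' @param calls Output of [call_rm_systems()].
#' @param genome_id Optional genome to restrict to (default: all calls).
#' @return Character vector of distinct normalised motifs (sorted).
#' @export
unique_genome_targets <- function(calls, genome_id = NULL) {
  if (is.null(calls) || nrow(calls) == 0L) return(character(0L))
  if (!is.null(genome_id))
    calls <- calls[calls$genome_id %in% genome_id, , drop = FALSE]
  sort(unique(calls$motif), method = "radix")
}

#' Find orphan MTases in a proteome
#'
#' An orphan MTase is an MTase hit with no REase hit recognising the same
#' normalised target within `max_gene_distance` genes on the same replicon.
#' Orphans can protect a plasmid from restriction without any cutting
#' activity.
#'
#' @inheritParams find_enzyme_hits
#' @param max_gene_distance Pairing window (default 4).
#' @return data.frame of orphan MTase hits (subset of [find_enzyme_hits()]
#'   rows).
#' @export
find_orphan_mtases <- function(proteome, db, tier = "all", max_gene_distance = 4L) {
  hits <- find_enzyme_hits(proteome, db, tier)
  orphan_mtases_from_hits(hits, max_gene_distance)
}

#' Identify orphan MTases among precomputed hits
#' @param hits Output of [find_enzyme_hits()].
#' @param max_gene_distance Pairing window (default 4).
#' @return data.frame of MTase hits with no cognate REase in the window.
#' @export
orphan_mtases_from_hits <- function(hits, max_gene_distance = 4L) {
  mt <- hits[hits$class == "MTase", , drop = FALSE]
  if (nrow(mt) == 0L) return(mt)
  re <- hits[hits$class == "REase", , drop = FALSE]
  paired <- vapply(seq_len(nrow(mt)), function(i) {
    any(re$genome_id == mt$genome_id[i] &
          re$replicon_id == mt$replicon_id[i] &
          re$motif_norm == mt$motif_norm[i] &
          abs(re$ordinal - mt$ordinal[i]) <= max_gene_distance)
  }, logical(1L))
  mt[!paired, , drop = FALSE]
}
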