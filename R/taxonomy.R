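# Species x target presence/absence matrix and the taxonomic target
# dictionary: for each species, the nested sets of R-M targets observed at
# ranks species, genus, family, order, class, phylum, kingdom. Only presence
# is used — a target counts for a species if any one of its genomes carries a
# system recognising it; prevalence is deliberately ignored.

TAXONOMIC_RANKS <- c("species", "genus", "family", "order", "class",
                     "phylum", "kingdom")

validate_taxonomy <- function(taxonomy) {
  miss <- setdiff(TAXONOMIC_RANKS, names(taxonomy))
  if (length(miss))
    stop("taxonomy lacks rank columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(taxonomy$species))
    stop("duplicate species in taxonomy table", call. = FALSE)
  empties <- vapply(TAXONOMIC_RANKS, function(r)
    any(is.na(taxonomy[[r]]) | !nzchar(taxonomy[[r]])), logical(1L))
  if (any(empties))
    stop("empty values in taxonomy ranks: ",
         paste(TAXONOMIC_RANKS[empties], collapse = ", "), call. = FALSE)
  invisible(taxonomy)
}

#' Build the species x k-mer target presence/absence matrix
#'
#' Each genome's recognised motifs (normalised IUPAC) are expanded into
#' unambiguous k-mers; motifs of a different length are excluded (each word
#' length is analysed separately). An entry is 1 iff at least one genome of
#' the species yielded a system whose expanded motif contains the k-mer —
#' presence only, never prevalence.
#'
#' @param genome_targets Named list: genome id -> character vector of motifs
#'   (IUPAC, typically from [unique_genome_targets()]).
#' @param genome_species Named character vector mapping genome id -> species.
#' @param k Target word length for this matrix (typically 4, 5 or 6).
#' @param species Optional character vector of all species to include as rows
#'   (default: those in `genome_species`); species with no targets get
#'   all-zero rows.
#' @return Binary integer matrix, rows = species, columns = sorted k-mers.
#' @export
build_presence_matrix <- function(genome_targets, genome_species, k,
                                  species = NULL) {
  unknown <- setdiff(names(genome_targets), names(genome_species))
  if (length(unknown))
    stop("genomes with unknown species: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(species)) species <- sort(unique(unname(genome_species)))
  per_genome <- lapply(genome_targets, function(motifs) {
    motifs <- motifs[nchar(motifs) == k]
    if (!length(motifs)) return(character(0L))
    sort(unique(unlist(lapply(motifs, expand_iupac))))
  })
  all_kmers <- sort(unique(unlist(per_genome)), method = "radix")
  mat <- matrix(0L, nrow = length(species), ncol = length(all_kmers),
                dimnames = list(species, all_kmers))
  for (g in names(per_genome)) {
    sp <- genome_species[[g]]
    if (length(per_genome[[g]]))
      mat[sp, per_genome[[g]]] <- 1L
  }
  mat
}

#' Target set of a species at a taxonomic level
#'
#' The union of presence-matrix rows over all species sharing the query
#' species' value at the given rank. At `"species"` this is the species' own
#' row; at `"kingdom"` it is the union over the whole dataset (every k-mer
#' targeted by any detected system).
#'
#' @param species Query species (must be a matrix row and in the taxonomy).
#' @param level One of `"species"`, `"genus"`, `"family"`, `"order"`,
#'   `"class"`, `"phylum"`, `"kingdom"`.
#' @param matrix Presence matrix from [build_presence_matrix()].
#' @param taxonomy data.frame with the seven rank columns.
#' @return Character vector of k-mers (sorted).
#' @export
targets_at_level <- function(species, level, matrix, taxonomy) {
  if (!level %in% TAXONOMIC_RANKS)
    stop("unknown taxonomic rank: ", level, call. = FALSE)
  validate_taxonomy(taxonomy)
  if (!species %in% taxonomy$species)
    stop("species not in taxonomy: ", species, call. = FALSE)
  if (!species %in% rownames(matrix))
    stop("species not in presence matrix: ", species, call. = FALSE)
  value <- taxonomy[[level]][taxonomy$species == species]
  members <- taxonomy$species[taxonomy[[level]] == value]
  members <- intersect(members, rownames(matrix))
  if (ncol(matrix) == 0L) return(character(0L))
  sub <- matrix[members, , drop = FALSE]
  sort(colnames(sub)[colSums(sub) > 0], method = "radix")
}

#' Build the taxonomic target dictionary
#'
#' For every species, the target sets at all seven ranks. Sets are nested
#' non-decreasing with level; the kingdom-level set is the union of all
#' targets detected anywhere in the dataset.
#'
#' @inheritParams targets_at_level
#' @return A `taxonomic_dictionary`: named list (per species) of named lists
#'   (per rank) of k-mer character vectors.
#' @export
build_dictionary <- function(matrix, taxonomy) {
  validate_taxonomy(taxonomy)
  miss <- setdiff(rownames(matrix), taxonomy$species)
  if (length(miss))
    stop("matrix species missing from taxonomy: ", paste(miss, collapse = ", "),
         call. = FALSE)
  out <- lapply(rownames(matrix), function(sp) {
    sets <- lapply(TAXONOMIC_RANKS, function(lv)
      targets_at_level(sp, lv, matrix, taxonomy))
    names(sets) <- TAXONOMIC_RANKS
    sets
  })
  names(out) <- rownames(matrix)
  structure(out, class = "taxonomic_dictionary")
}

#' @export
print.taxonomic_dictionary <- function(x, ...) {
  cat(sprintf("taxonomic_dictionary: %d species, %d kingdom-level targets\n",
              length(x),
              if (length(x)) length(x[[1L]]$kingdom) else 0L))
  invisible(x)
}

#' Read a seven-rank taxonomy table from TSV
#' @param path TSV with columns species, genus, family, order, class, phylum,
#'   kingdom.
#' @return Validated data.frame.
#' @export
read_taxonomy <- function(path) {
  tx <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_taxonomy(tx)
  tx
}

#' Write a presence matrix as TSV (species rows, k-mer columns)
#' @param matrix Presence matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_presence_matrix <- function(matrix, path) {
  df <- data.frame(species = rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
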