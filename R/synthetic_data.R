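# Seeded generators for every input the pipeline consumes, with planted
# ground truth for recovery tests: Markov DNA with tunable target depletion,
# protein families mutated to controlled percent identity, taxonomies with
# hierarchical structure, and plasmid/PTU tables with planted effects.
# Every generator is a pure function of (config, seed).

DNA_BASES <- c("A", "C", "G", "T")

#' Generate a Markov-chain DNA sequence
#'
#' @param length Output length in bases.
#' @param order Markov order (0 = i.i.d.).
#' @param composition For order 0, a probability vector of length 4 (A,C,G,T;
#'   default uniform). For order >= 1, a 4^order x 4 transition matrix with
#'   rows named by context words in lexicographic order (default uniform);
#'   the initial context is drawn from the uniform distribution over
#'   contexts.
#' @param seed Integer seed.
#' @return A DNA string of exactly `length` bases.
#' @export
generate_markov_sequence <- function(length, order = 0L, composition = NULL,
                                     seed = 1L) {
  stopifnot(length >= 1, order >= 0)
  order <- as.integer(order)
  if (order == 0L) {
    p <- if (is.null(composition)) rep(0.25, 4L) else as.numeric(composition)
    if (length(p) != 4L || any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop("composition must be 4 non-negative probabilities summing to 1",
           call. = FALSE)
    return(with_seed(seed, paste(sample(DNA_BASES, length, replace = TRUE,
                                        prob = p), collapse = "")))
  }
  contexts <- Biostrings::mkAllStrings(DNA_BASES, order)
  if (is.null(composition)) {
    trans <- matrix(0.25, nrow = length(contexts), ncol = 4L,
                    dimnames = list(contexts, DNA_BASES))
  } else {
    trans <- as.matrix(composition)
    if (nrow(trans) != length(contexts) || ncol(trans) != 4L ||
        any(trans < 0) || any(abs(rowSums(trans) - 1) > 1e-8))
      stop(sprintf("transition matrix must be %d x 4 with rows summing to 1",
                   length(contexts)), call. = FALSE)
    if (is.null(rownames(trans))) rownames(trans) <- contexts
    trans <- trans[contexts, , drop = FALSE]
    colnames(trans) <- DNA_BASES
  }
  cum <- t(apply(trans, 1L, cumsum))
  with_seed(seed, {
    start <- sample(contexts, 1L)
    out <- integer(length)
    init <- match(strsplit(start, "")[[1L]], DNA_BASES)
    n_init <- min(order, length)
    out[seq_len(n_init)] <- init[seq_len(n_init)]
    if (length > order) {
      u <- stats::runif(length - order)
      # context index in lexicographic (base-4) encoding
      ctx <- sum((init - 1L) * 4L^rev(seq_len(order) - 1L)) + 1L
      for (i in (order + 1L):length) {
        b <- findInterval(u[i - order], cum[ctx, ], left.open = TRUE) + 1L
        out[i] <- b
        ctx <- ((ctx - 1L) %% 4L^(order - 1L)) * 4L + b  # shift context left
      }
    }
    paste(DNA_BASES[out], collapse = "")
  })
}

#' Destroy a fraction of a word's occurrences by single-base substitution
#'
#' Emulates selection against a restriction target: a fraction `f` of the
#' word's occurrences (rounded to nearest, chosen uniformly by seed) are each
#' destroyed by one substitution of the word's middle base, with the
#' replacement base chosen so that no new occurrence of the word is created.
#' Occurrence subsets are nested in `f` for a fixed seed, so counts are
#' non-increasing in `f`. Length is always preserved; `f = 1` guarantees zero
#' remaining occurrences (repeated passes if overlaps regenerate matches).
#'
#' @param sequence DNA string.
#' @param word Unambiguous DNA word.
#' @param f Fraction of occurrences to destroy, in [0, 1].
#' @param seed Integer seed.
#' @return The modified sequence (same length).
#' @export
deplete_word <- function(sequence, word, f, seed = 1L) {
  assert_dna_word(word)
  stopifnot(f >= 0, f <= 1)
  if (f == 0) return(sequence)
  k <- nchar(word)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  L <- length(chars)
  pass <- 0L
  repeat {
    pass <- pass + 1L
    starts <- find_occurrences(chars, word)
    n <- length(starts)
    if (n == 0L) break
    m <- if (f >= 1) n else round(f * n)
    if (m == 0L) break
    chosen <- with_seed(seed + pass - 1L,
                        starts[sample.int(length(starts))])[seq_len(m)]
    for (s in chosen) {
      # overlapping edits may already have destroyed this occurrence
      if (paste(chars[s:(s + k - 1L)], collapse = "") != word) next
      chars <- destroy_occurrence(chars, word, s, seed + s)
    }
    if (f < 1) break
  }
  if (f >= 1 && length(find_occurrences(chars, word)) > 0L)
    warning("could not remove every occurrence of '", word, "'",
            call. = FALSE)
  paste(chars, collapse = "")
}

find_occurrences <- function(chars, word) {
  k <- nchar(word)
  L <- length(chars)
  if (L < k) return(integer(0L))
  s <- paste(chars, collapse = "")
  as.integer(Biostrings::start(Biostrings::matchPattern(
    word, Biostrings::DNAString(s), fixed = TRUE)))
}

# Substitute one base inside the occurrence at `s` so the occurrence is
# destroyed and no new occurrence of `word` appears in the affected window.
# Tries the middle base first (least likely to complete a shifted copy),
# then every other position; warns and skips if nothing works.
destroy_occurrence <- function(chars, word, s, seed) {
  k <- nchar(word)
  L <- length(chars)
  mid <- s + (k %/% 2L)
  positions <- unique(c(mid, s:(s + k - 1L)))
  win_lo <- max(1L, s - k + 1L)
  win_hi <- min(L, s + 2L * k - 2L)
  before <- count_in_window(chars, word, win_lo, win_hi)
  cand_order <- with_seed(seed, lapply(positions, function(p)
    sample(setdiff(DNA_BASES, chars[p]))))
  for (pi in seq_along(positions)) {
    p <- positions[[pi]]
    for (b in cand_order[[pi]]) {
      trial <- chars
      trial[p] <- b
      if (count_in_window(trial, word, win_lo, win_hi) < before)
        return(trial)
    }
  }
  warning("impossible substitution at position ", s, "; occurrence skipped",
          call. = FALSE)
  chars
}

count_in_window <- function(chars, word, lo, hi) {
  sub <- paste(chars[lo:hi], collapse = "")
  count_overlapping(sub, word)
}

#' Random protein sequence over the 20-letter alphabet
#' @param length Number of residues.
#' @param seed Integer seed.
#' @return Amino-acid string.
#' @export
random_protein <- function(length, seed = 1L) {
  with_seed(seed, paste(sample(AA20, length, replace = TRUE), collapse = ""))
}

#' Mutate a protein down to a target percent identity
#'
#' Random substitutions are applied one at a time until the measured
#' global-alignment identity to the original first falls to or below
#' `target_identity`; the realised identity is returned alongside the mutant
#' so tests can condition on measured, not nominal, identity.
#'
#' @param protein Amino-acid string.
#' @param target_identity Target percent identity in (0, 100].
#' @param seed Integer seed.
#' @return List with `sequence` and `identity` (realised, via
#'   [percent_identity()]).
#' @export
mutate_protein_to_identity <- function(protein, target_identity, seed = 1L) {
  stopifnot(target_identity > 0, target_identity <= 100)
  if (target_identity >= 100)
    return(list(sequence = protein, identity = 100))
  chars <- strsplit(protein, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  with_seed(seed, {
    identity <- 100
    guard <- 0L
    while (identity > target_identity && guard < 20L * n) {
      guard <- guard + 1L
      p <- sample.int(n, 1L)
      chars[p] <- sample(setdiff(AA20, chars[p]), 1L)
      identity <- percent_identity(protein, paste(chars, collapse = ""))
    }
    list(sequence = paste(chars, collapse = ""), identity = identity)
  })
}

#' Generate a mock enzyme reference database and proteomes with planted systems
#'
#' Builds a reference of random MTase/REase proteins with assigned recognition
#' motifs and evidence tiers, then a proteome per planted genome embedding
#' copies of those enzymes mutated to requested identities, at gene positions
#' that respect or violate the 4-gene pairing window by design. The returned
#' truth table records every plant with its realised identities, from which
#' expected detectability follows without re-running generation.
#'
#' @param config List with elements (all optional except `plants`):
#'   `seed` (default 1), `protein_length` (default 120),
#'   `motifs` (character vector, one per system id used in `plants`;
#'   default a panel of palindromic and degenerate motifs),
#'   `tiers` (per system; default cycling gold/nonputative/putative),
#'   `plants`: data.frame with columns `genome_id`, `system` (index into
#'   motifs), `mtase_identity`, `rease_identity` (NA = REase absent, i.e. an
#'   orphan plant), `gap` (ordinal distance MTase -> REase).
#' @return List with `db` (reference data.frame), `proteome` (data.frame of
#'   ordered genes), and `truth` (one row per plant: positions, realised
#'   identities, expected hit/call flags at the default thresholds).
#' @export
generate_enzyme_db_and_proteomes <- function(config = list()) {
  seed <- config$seed %||% 1L
  plen <- config$protein_length %||% 120L
  motifs <- config$motifs %||% c("GAATTC", "GGATCC", "AAGCTT", "GANTC",
                                 "CCWGG", "CATG")
  plants <- config$plants
  if (is.null(plants))
    plants <- data.frame(genome_id = "G1", system = c(1L, 2L, 3L),
                         mtase_identity = c(100, 100, 100),
                         rease_identity = c(100, NA, 100),
                         gap = c(1L, NA, 6L))
  n_sys <- length(motifs)
  tiers <- config$tiers %||%
    rep(c("gold", "nonputative", "putative"), length.out = n_sys)
  db <- data.frame(
    id = c(sprintf("M.Enz%03d", seq_len(n_sys)),
           sprintf("R.Enz%03d", seq_len(n_sys))),
    class = rep(c("MTase", "REase"), each = n_sys),
    sequence = vapply(seq_len(2L * n_sys), function(i)
      random_protein(plen, mix_seed(seed, 4L, i)), character(1L)),
    motif = rep(motifs, 2L),
    tier = rep(tiers, 2L),
    stringsAsFactors = FALSE)

  genes <- list(); truth <- list()
  for (gid in unique(plants$genome_id)) {
    pl <- plants[plants$genome_id == gid, , drop = FALSE]
    ordinal <- 0L
    add_gene <- function(sequence, tag) {
      ordinal <<- ordinal + 1L
      genes[[length(genes) + 1L]] <<- data.frame(
        genome_id = gid, replicon_id = "chr1", ordinal = ordinal,
        protein_id = sprintf("%s_g%03d_%s", gid, ordinal, tag),
        sequence = sequence, stringsAsFactors = FALSE)
      ordinal
    }
    add_filler <- function(n) for (i in seq_len(n))
      add_gene(random_protein(plen, mix_seed(seed, 5L, length(genes) + 1L)), "fill")
    add_filler(2L)
    for (i in seq_len(nrow(pl))) {
      sys <- pl$system[i]
      mt_ref <- db$sequence[db$class == "MTase"][sys]
      mt <- mutate_protein_to_identity(mt_ref, pl$mtase_identity[i],
                                       mix_seed(seed, 6L, i))
      mt_pos <- add_gene(mt$sequence, "mtase")
      re_pos <- NA_integer_; re_ident <- NA_real_
      if (!is.na(pl$rease_identity[i])) {
        add_filler(pl$gap[i] - 1L)
        re_ref <- db$sequence[db$class == "REase"][sys]
        re <- mutate_protein_to_identity(re_ref, pl$rease_identity[i],
                                         mix_seed(seed, 7L, i))
        re_pos <- add_gene(re$sequence, "rease")
        re_ident <- re$identity
      }
      mt_hit <- mt$identity >= MTASE_IDENTITY_MIN
      re_hit <- !is.na(re_ident) && re_ident >= REASE_IDENTITY_MIN
      callable <- mt_hit && re_hit && !is.na(pl$gap[i]) && pl$gap[i] <= 4L
      truth[[length(truth) + 1L]] <- data.frame(
        genome_id = gid, system = sys, motif = motifs[sys],
        motif_norm = normalise_motif(motifs[sys]),
        tier = tiers[sys],
        mtase_ordinal = mt_pos, rease_ordinal = re_pos,
        mtase_identity = mt$identity, rease_identity = re_ident,
        gap = pl$gap[i],
        mtase_detectable = mt_hit, rease_detectable = re_hit,
        system_detectable = callable,
        orphan_mtase = mt_hit && !callable,
        stringsAsFactors = FALSE)
      add_filler(5L)  # keep plants out of each other's pairing windows
    }
  }
  list(db = db, proteome = do.call(rbind, genes),
       truth = do.call(rbind, truth))
}

#' Generate a hierarchical taxonomy for n species
#'
#' Species are grouped pairwise up the ranks (genus, family, order, class,
#' phylum) after a seeded shuffle, yielding a balanced nested taxonomy with
#' kingdom fixed to Bacteria.
#'
#' @param n_species Number of species.
#' @param seed Integer seed.
#' @param group_size Species per genus, genera per family, etc. (default 2).
#' @return Taxonomy data.frame with the seven rank columns.
#' @export
generate_taxonomy <- function(n_species, seed = 1L, group_size = 2L) {
  sp <- sprintf("s%02d", seq_len(n_species))
  ord <- with_seed(seed, sample.int(n_species))
  idx <- integer(n_species)
  idx[ord] <- seq_len(n_species)
  grp <- function(i) ceiling(i / group_size)
  genus  <- grp(idx); family <- grp(genus); order_ <- grp(family)
  class_ <- grp(order_); phylum <- grp(class_)
  data.frame(species = sp,
             genus = sprintf("g%02d", genus),
             family = sprintf("f%02d", family),
             order = sprintf("o%02d", order_),
             class = sprintf("c%02d", class_),
             phylum = sprintf("p%02d", phylum),
             kingdom = "Bacteria", stringsAsFactors = FALSE)
}

#' Generate a random species x k-mer presence matrix
#'
#' Used for property tests over randomised worlds (e.g. dictionary nesting).
#'
#' @param species Character vector of species names.
#' @param kmers Candidate target words.
#' @param p Per-entry presence probability.
#' @param seed Integer seed.
#' @return Binary matrix, species rows x k-mer columns.
#' @export
generate_random_presence <- function(species, kmers, p = 0.1, seed = 1L) {
  with_seed(seed, matrix(stats::rbinom(length(species) * length(kmers), 1L, p),
                         nrow = length(species),
                         dimnames = list(species, kmers)))
}

#' Synthetic PTU summary table with planted regression effects
#'
#' Host-range classes, median lengths (log-uniform 2-200 kb) and member
#' counts are drawn at random; the response is the planted linear combination
#' plus Gaussian noise, for coefficient-recovery tests of the PTU model.
#'
#' @param n Number of PTUs.
#' @param beta_host,beta_len,beta_n Planted coefficients on numeric host
#'   range, log10 median length, and member count.
#' @param sigma Residual standard deviation.
#' @param seed Integer seed.
#' @return data.frame ready for [fit_ptu_model()], with the planted betas as
#'   attributes.
#' @export
generate_ptu_table <- function(n = 200L, beta_host = -0.5, beta_len = 0.8,
                               beta_n = 0, sigma = 0.1, seed = 1L) {
  with_seed(seed, {
    host <- sample(1:6, n, replace = TRUE)
    med_len <- 10^stats::runif(n, log10(2e3), log10(2e5))
    n_pl <- stats::rpois(n, 10) + 4L
    resp <- beta_host * host + beta_len * log10(med_len) + beta_n * n_pl +
      stats::rnorm(n, 0, sigma)
    structure(data.frame(ptu = sprintf("PTU%03d", seq_len(n)),
                         response = resp, host_range = host,
                         median_length = med_len, n_plasmids = n_pl,
                         stringsAsFactors = FALSE),
              planted = c(host = beta_host, len = beta_len, n = beta_n,
                          sigma = sigma))
  })
}

#' Synthetic plasmid set with planted MTase-carriage effects
#'
#' Plasmid lengths are bimodal (small ~5 kb, large ~100 kb, lognormal
#' spread); the probability of carrying an orphan MTase follows a logistic
#' model increasing with log10 length and numeric host range.
#'
#' @param n Number of plasmids.
#' @param alpha,beta_len,beta_host Logistic carriage model parameters
#'   (intercept, log10-length slope, host-range slope).
#' @param seed Integer seed.
#' @return data.frame with `plasmid_id`, `length`, `ptu`, `host_range`
#'   (class labels I-VI), `host_range_numeric`, `n_orphan_mtases`; planted
#'   parameters as attribute `planted`.
#' @export
generate_plasmid_set <- function(n = 400L, alpha = -14, beta_len = 2.5,
                                 beta_host = 0.5, seed = 1L) {
  with_seed(seed, {
    small <- stats::runif(n) < 0.5
    len <- ifelse(small,
                  stats::rlnorm(n, log(5e3), 0.4),
                  stats::rlnorm(n, log(1e5), 0.4))
    host <- sample(1:6, n, replace = TRUE)
    p <- stats::plogis(alpha + beta_len * log10(len) + beta_host * host)
    carry <- stats::rbinom(n, 1L, p)
    ptu <- sprintf("PTU%02d", sample.int(max(4L, n %/% 10L), n, replace = TRUE))
    structure(data.frame(plasmid_id = sprintf("pl%04d", seq_len(n)),
                         length = round(len), ptu = ptu,
                         host_range = c("I", "II", "III", "IV", "V", "VI")[host],
                         host_range_numeric = host,
                         n_orphan_mtases = carry, stringsAsFactors = FALSE),
              planted = c(alpha = alpha, len = beta_len, host = beta_host))
  })
}

#' Default configuration for a synthetic world
#'
#' The defaults define the study conditions the generators emulate: 8 species
#' in a balanced taxonomy, 3 palindromic 6-bp targets per species drawn from
#' the 64-palindrome panel, 1 kb genes (30 core / 15 non-core / 15 plasmid
#' per genome), plasmid genes depleted of within-species targets at fraction
#' 0.8 (core and non-core undepleted), and graded depletion fractions
#' decreasing up the hierarchy for engineered plasmids.
#'
#' @param seed Integer seed.
#' @param ... Overrides for any default field.
#' @return Named list of world parameters.
#' @export
world_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = seed, n_species = 8L, k = 6L,
    n_targets_per_species = 3L,
    n_core_genes = 30L, n_noncore_genes = 15L, n_plasmid_genes = 15L,
    gene_length = 1000L,
    f_plasmid = 0.8, f_core = 0, f_noncore = 0,
    graded_f = c(species = 0.95, genus = 0.85, family = 0.7, order = 0.55,
                 class = 0.4, phylum = 0.25, kingdom = 0.1))
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Generate a synthetic world: taxonomy, targets, genomes and ground truth
#'
#' Each species receives a set of palindromic 6-bp targets; per species one
#' genome is generated with core, non-core and plasmid gene sequences.
#' Plasmid genes are depleted of the species' own targets at the configured
#' fraction (emulating selection by within-species restriction), core and
#' non-core genes at theirs (default none). The presence matrix and
#' taxonomic dictionary are built from the planted targets.
#'
#' @param config List from [world_config()].
#' @return List with `config`, `taxonomy`, `species_targets`,
#'   `presence_matrix`, `dictionary`, `genomes` (per species: data.frame of
#'   genes with `component` and `sequence`), and `genome_species` map.
#' @export
generate_world <- function(config = world_config()) {
  cfg <- config
  tx <- generate_taxonomy(cfg$n_species, cfg$seed)
  pal <- enumerate_palindromes(cfg$k)
  species_targets <- lapply(seq_len(cfg$n_species), function(i) {
    if (cfg$n_targets_per_species == 0L) return(character(0L))
    with_seed(mix_seed(cfg$seed, 3L, i),
              sort(sample(pal, cfg$n_targets_per_species)))
  })
  names(species_targets) <- tx$species

  genome_ids <- sprintf("%s_gen1", tx$species)
  genome_species <- stats::setNames(tx$species, genome_ids)
  mat <- build_presence_matrix(stats::setNames(species_targets, genome_ids),
                               genome_species, cfg$k, species = tx$species)
  dict <- build_dictionary(mat, tx)

  make_genes <- function(sp_i, comp, n_genes, f, rep_id) {
    sp <- tx$species[sp_i]
    targets <- species_targets[[sp]]
    comp_i <- match(comp, PANGENOME_COMPONENTS)
    vapply(seq_len(n_genes), function(j) {
      s <- generate_markov_sequence(cfg$gene_length, 0L, NULL,
                                    mix_seed(cfg$seed, 1L, sp_i, comp_i, j))
      if (f > 0) for (w in targets)
        s <- deplete_word(s, w, f, mix_seed(cfg$seed, 2L, sp_i, comp_i, j))
      s
    }, character(1L))
  }
  genomes <- lapply(seq_len(cfg$n_species), function(i) {
    core <- make_genes(i, "core", cfg$n_core_genes, cfg$f_core, "chr")
    ncore <- make_genes(i, "non-core", cfg$n_noncore_genes, cfg$f_noncore, "chr")
    plas <- make_genes(i, "plasmid", cfg$n_plasmid_genes, cfg$f_plasmid, "pl")
    data.frame(
      genome_id = genome_ids[i],
      replicon_id = rep(c("chr1", "chr1", "pl1"),
                        c(length(core), length(ncore), length(plas))),
      gene_id = sprintf("%s_%04d", genome_ids[i],
                        seq_len(length(core) + length(ncore) + length(plas))),
      component = rep(c("core", "non-core", "plasmid"),
                      c(length(core), length(ncore), length(plas))),
      sequence = c(core, ncore, plas), stringsAsFactors = FALSE)
  })
  names(genomes) <- tx$species

  list(config = cfg, taxonomy = tx, species_targets = species_targets,
       presence_matrix = mat, dictionary = dict, genomes = genomes,
       genome_species = genome_species)
}

#' Engineer a plasmid sequence with depletion graded by taxonomic level
#'
#' Emulates a plasmid shaped most strongly by the restriction systems of its
#' own species and progressively less by more distant ones: each target in
#' the species' kingdom-level set is depleted at the fraction configured for
#' the lowest rank at which it enters the species' dictionary.
#'
#' @param dictionary A `taxonomic_dictionary`.
#' @param species Species whose hierarchy drives the depletion.
#' @param length Plasmid length in bases.
#' @param graded_f Named depletion fractions per rank (see [world_config()]).
#' @param seed Integer seed.
#' @return DNA string of the requested length.
#' @export
generate_graded_plasmid <- function(dictionary, species, length = 50000L,
                                    graded_f = world_config()$graded_f,
                                    seed = 1L) {
  stopifnot(inherits(dictionary, "taxonomic_dictionary"))
  sets <- dictionary[[species]]
  s <- generate_markov_sequence(length, 0L, NULL, seed)
  seen <- character(0L)
  for (lv in TAXONOMIC_RANKS) {
    new <- setdiff(sets[[lv]], seen)
    for (w in new)
      s <- deplete_word(s, w, graded_f[[lv]], seed + utf8ToInt(substr(w, 1, 1)))
    seen <- union(seen, new)
  }
  s
}

`%||%` <- function(a, b) if (is.null(a)) b else a
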