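# Downstream analyses: pangenome component splitting, per-component avoidance
# across the taxonomic hierarchy, target density vs plasmid size, plasmid
# taxonomic unit (PTU) host-range models, and MTase carriage summaries.

PANGENOME_COMPONENTS <- c("core", "non-core", "plasmid")
SIZE_BIN_BREAKS <- c(0, 10e3, 20e3, 50e3, 100e3, Inf)
SIZE_BIN_LABELS <- c("<10kb", "10-20kb", "20-50kb", "50-100kb", ">100kb")
CORE_FRACTION_MIN <- 0.99  # strict: core iff fraction > 0.99

#' Classify gene families as core or non-core
#'
#' A family is core iff the fraction of genomes carrying exactly one member
#' strictly exceeds 0.99 (relaxed single-copy core: one bad assembly cannot
#' eject a family from the core).
#'
#' @param pangenome data.frame with columns `family`, `genome_id`, `count`
#'   (copy number of the family in that genome; absent rows mean 0 copies).
#' @param genomes Optional character vector of all genome ids in the dataset
#'   (default: those present in `pangenome`).
#' @return data.frame with columns `family`, `n_single_copy`, `fraction`,
#'   `core` (logical).
#' @export
classify_core_families <- function(pangenome, genomes = NULL) {
  need <- c("family", "genome_id", "count")
  miss <- setdiff(need, names(pangenome))
  if (length(miss))
    stop("pangenome table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  stopifnot(all(pangenome$count >= 0))
  if (is.null(genomes)) genomes <- unique(pangenome$genome_id)
  n_genomes <- length(genomes)
  single <- pangenome[pangenome$count == 1L & pangenome$genome_id %in% genomes, ,
                      drop = FALSE]
  n_single <- table(factor(single$family, levels = unique(pangenome$family)))
  frac <- as.numeric(n_single) / n_genomes
  data.frame(family = names(n_single),
             n_single_copy = as.integer(n_single),
             fraction = frac,
             core = frac > CORE_FRACTION_MIN,
             stringsAsFactors = FALSE)
}

#' Assign each gene of a genome to a pangenome component
#'
#' Genes on plasmids and secondary chromosomes are component `"plasmid"`
#' regardless of family; chromosomal genes are `"core"` or `"non-core"` by
#' their family's core status.
#'
#' @param genes data.frame with columns `genome_id`, `replicon_id`, `family`
#'   (and any others, carried through).
#' @param core_families Output of [classify_core_families()] (or any
#'   data.frame with `family` and logical `core`).
#' @param replicon_map data.frame with columns `genome_id`, `replicon_id`,
#'   `replicon_type` in `chromosome`/`plasmid`/`secondary_chromosome`.
#' @return `genes` with an added `component` column.
#' @export
assign_components <- function(genes, core_families, replicon_map) {
  unknown <- setdiff(unique(genes$genome_id), unique(replicon_map$genome_id))
  if (length(unknown))
    stop("genomes absent from replicon map: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  key <- paste(replicon_map$genome_id, replicon_map$replicon_id, sep = "\r")
  rtype <- stats::setNames(replicon_map$replicon_type, key)
  gkey <- paste(genes$genome_id, genes$replicon_id, sep = "\r")
  if (any(is.na(rtype[gkey])))
    stop("replicons absent from replicon map: ",
         paste(unique(genes$replicon_id[is.na(rtype[gkey])]), collapse = ", "),
         call. = FALSE)
  is_core <- stats::setNames(core_families$core, core_families$family)
  fam_core <- is_core[genes$family]
  fam_core[is.na(fam_core)] <- FALSE  # family unseen in pangenome -> non-core
  component <- ifelse(rtype[gkey] != "chromosome", "plasmid",
                      ifelse(fam_core, "core", "non-core"))
  genes$component <- unname(component)
  genes
}

#' Per-component, per-level avoidance profile of one genome
#'
#' For each pangenome component with enough sequence, the component's genes
#' are subsampled to a fixed length and the median exceptionality score is
#' computed for the species' target set at every taxonomic level.
#'
#' @param genes data.frame with columns `component` and `sequence` (gene DNA).
#' @param species The genome's species (dictionary key).
#' @param dictionary A `taxonomic_dictionary` built for word length `k`.
#' @param k Target word length.
#' @param subsample_length Fixed length in bases each component is subsampled
#'   to (components with less total sequence are excluded).
#' @param seed Integer seed for the subsampling draws.
#' @return data.frame with columns `component`, `level`, `n_targets`,
#'   `median_z`, `flag` (`"ok"`, `"undefined"` for empty target sets,
#'   `"insufficient_sequence"` for excluded components).
#' @export
component_avoidance_profile <- function(genes, species, dictionary, k,
                                        subsample_length = 50000L, seed = 1L) {
  stopifnot(inherits(dictionary, "taxonomic_dictionary"))
  if (!species %in% names(dictionary))
    stop("species not in dictionary: ", species, call. = FALSE)
  levels_sets <- dictionary[[species]]
  rows <- list()
  for (comp in PANGENOME_COMPONENTS) {
    gs <- genes$sequence[genes$component == comp]
    sub <- if (length(gs)) subsample_genes(gs, subsample_length, seed) else
      structure(NA_character_, excluded = TRUE)
    if (is.na(sub)) {
      rows[[length(rows) + 1L]] <- data.frame(
        component = comp, level = TAXONOMIC_RANKS, n_targets = NA_integer_,
        median_z = NA_real_, flag = "insufficient_sequence",
        stringsAsFactors = FALSE)
      next
    }
    counts <- build_count_table(sub, k)
    for (lv in TAXONOMIC_RANKS) {
      targets <- levels_sets[[lv]]
      targets <- targets[nchar(targets) == k]
      sc <- score_target_group(counts, targets, label = lv)
      rows[[length(rows) + 1L]] <- data.frame(
        component = comp, level = lv, n_targets = length(targets),
        median_z = sc$median_z, flag = sc$flag, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Plasmid size bin
#' @param length_bp Plasmid length(s) in bases.
#' @return Factor with levels `<10kb`, `10-20kb`, `20-50kb`, `50-100kb`,
#'   `>100kb`.
#' @export
size_bin <- function(length_bp) {
  cut(length_bp, breaks = SIZE_BIN_BREAKS, labels = SIZE_BIN_LABELS,
      right = FALSE)
}

#' Mean target density of a plasmid sequence
#'
#' Mean over the target words of count / L (occurrences per base). The
#' random-sequence reference density for one k-mer is 4^-k.
#'
#' @param sequence Plasmid DNA sequence.
#' @param targets Character vector of unambiguous target words.
#' @param id Optional plasmid id carried through.
#' @return One-row data.frame: `plasmid_id`, `length`, `n_targets`,
#'   `mean_density`, `size_bin`, `flag`.
#' @export
target_density <- function(sequence, targets, id = NA_character_) {
  L <- nchar(sequence)
  if (length(targets) == 0L) {
    return(data.frame(plasmid_id = id, length = L, n_targets = 0L,
                      mean_density = NA_real_, size_bin = size_bin(L),
                      flag = "undefined", stringsAsFactors = FALSE))
  }
  counts <- vapply(targets, function(w) count_overlapping(sequence, w),
                   integer(1L))
  data.frame(plasmid_id = id, length = L, n_targets = length(targets),
             mean_density = mean(counts / L), size_bin = size_bin(L),
             flag = "ok", stringsAsFactors = FALSE)
}

#' Per-species, per-size-bin median target densities
#'
#' Cells supported by 5 or fewer plasmids are suppressed (only size/species
#' combinations with more than 5 plasmids are reported).
#'
#' @param records data.frame with columns `species`, `size_bin`,
#'   `mean_density` (one row per plasmid, e.g. stacked [target_density()]
#'   rows with a species column added).
#' @param min_n Minimum cell size; cells with `n <= min_n` are dropped
#'   (default 5, strict).
#' @return data.frame: `species`, `size_bin`, `n`, `median_density`.
#' @export
density_size_summary <- function(records, min_n = 5L) {
  recs <- records[!is.na(records$mean_density), , drop = FALSE]
  if (nrow(recs) == 0L)
    return(data.frame(species = character(), size_bin = character(),
                      n = integer(), median_density = numeric(),
                      stringsAsFactors = FALSE))
  agg <- stats::aggregate(mean_density ~ species + size_bin, data = recs,
                          FUN = stats::median)
  n <- stats::aggregate(mean_density ~ species + size_bin, data = recs,
                        FUN = length)
  out <- data.frame(species = agg$species, size_bin = agg$size_bin,
                    n = n$mean_density, median_density = agg$mean_density,
                    stringsAsFactors = FALSE)
  out <- out[out$n > min_n, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Numeric coding of PTU host-range classes
#'
#' Classes I (within-species, narrowest) through VI (within-phylum, broadest)
#' map to 1..6; unassigned plasmids are excluded from host-range models and
#' map to `NA`.
#'
#' @param class Character vector of classes (`"I"`..`"VI"` or
#'   `"unassigned"`).
#' @return Integer vector (NA for unassigned).
#' @export
host_range_numeric <- function(class) {
  coding <- c(I = 1L, II = 2L, III = 3L, IV = 4L, V = 5L, VI = 6L)
  out <- coding[as.character(class)]
  bad <- !is.na(class) & class != "unassigned" & is.na(out)
  if (any(bad))
    stop("unknown host-range class: ",
         paste(unique(class[bad]), collapse = ", "), call. = FALSE)
  unname(out)
}

#' Ordinary least squares model of PTU avoidance
#'
#' Fits mean exceptionality of a target group per PTU on numeric host range,
#' log10 median plasmid length, and number of member plasmids. A separate fit
#' per taxonomic level of targets is the intended use.
#'
#' @param ptu data.frame with columns `response` (mean exceptionality),
#'   `host_range` (numeric 1-6), `median_length` (bp), `n_plasmids`.
#' @param level Optional label for the target level modelled.
#' @return A `ptu_model_fit`: list with `level`, `n`, `coefficients`
#'   (data.frame term/estimate/se), `r_squared`, and the underlying `lm` fit.
#' @export
fit_ptu_model <- function(ptu, level = NA_character_) {
  need <- c("response", "host_range", "median_length", "n_plasmids")
  miss <- setdiff(need, names(ptu))
  if (length(miss))
    stop("PTU table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  ptu <- ptu[stats::complete.cases(ptu[, need]), , drop = FALSE]
  if (nrow(ptu) < 10L)
    stop("need at least 10 PTUs with complete covariates", call. = FALSE)
  ptu$log10_median_length <- log10(ptu$median_length)
  fit <- stats::lm(response ~ host_range + log10_median_length + n_plasmids,
                   data = ptu)
  if (any(is.na(stats::coef(fit)))) {
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear terms: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)
  r2 <- sm$r.squared
  # constant response: nothing to explain (guards against an unreliable
  # summary() on an exact fit)
  if (!is.finite(r2) || stats::var(ptu$response) == 0) r2 <- 0
  structure(list(
    level = level, n = nrow(ptu),
    coefficients = data.frame(term = rownames(sm$coefficients),
                              estimate = sm$coefficients[, "Estimate"],
                              se = sm$coefficients[, "Std. Error"],
                              row.names = NULL, stringsAsFactors = FALSE),
    r_squared = r2,
    fit = fit), class = "ptu_model_fit")
}

#' @export
print.ptu_model_fit <- function(x, ...) {
  cat(sprintf("ptu_model_fit (level %s): n = %d, R^2 = %.3f\n",
              x$level, x$n, x$r_squared))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' MTase carriage by plasmid size and host range
#'
#' Tabulates, per size bin x host-range class, the proportion of plasmids
#' carrying at least one orphan MTase, and per PTU the orphan-MTase density
#' (MTases per kb of plasmid sequence).
#'
#' @param plasmids data.frame with columns `plasmid_id`, `length` (bp),
#'   `ptu`, `host_range` (class labels), `n_orphan_mtases`.
#' @return List with `carriage` (size_bin, host_range, n_with_mtase, n_total,
#'   proportion) and `ptu_density` (ptu, n_plasmids, total_kb, n_orphans,
#'   mtases_per_kb).
#' @export
mtase_carriage_summary <- function(plasmids) {
  need <- c("plasmid_id", "length", "ptu", "host_range", "n_orphan_mtases")
  miss <- setdiff(need, names(plasmids))
  if (length(miss))
    stop("plasmid table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  plasmids$size_bin <- size_bin(plasmids$length)
  plasmids$has_mtase <- plasmids$n_orphan_mtases > 0L
  grid <- expand.grid(size_bin = SIZE_BIN_LABELS,
                      host_range = sort(unique(plasmids$host_range)),
                      stringsAsFactors = FALSE)
  carriage <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    sel <- plasmids$size_bin == grid$size_bin[i] &
      plasmids$host_range == grid$host_range[i]
    n <- sum(sel)
    data.frame(size_bin = grid$size_bin[i], host_range = grid$host_range[i],
               n_with_mtase = sum(plasmids$has_mtase[sel]), n_total = n,
               proportion = if (n > 0) sum(plasmids$has_mtase[sel]) / n
                            else NA_real_,
               flag = if (n > 0) "ok" else "empty_bin",
               stringsAsFactors = FALSE)
  }))
  ptus <- sort(unique(plasmids$ptu))
  ptu_density <- do.call(rbind, lapply(ptus, function(p) {
    sel <- plasmids$ptu == p
    kb <- sum(plasmids$length[sel]) / 1000
    data.frame(ptu = p, n_plasmids = sum(sel), total_kb = kb,
               n_orphans = sum(plasmids$n_orphan_mtases[sel]),
               mtases_per_kb = sum(plasmids$n_orphan_mtases[sel]) / kb,
               stringsAsFactors = FALSE)
  }))
  list(carriage = carriage, ptu_density = ptu_density)
}
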