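# One reproducible run: simulate -> detect -> dictionary -> score -> analyze,
# with a validated config and a JSON run manifest (inputs, seeds, checksums).
# Stages are exposed individually so analysis scripts can drive them; stage
# outputs are plain TSV with stable column contracts.

ALLOWED_K <- c(4L, 5L, 6L)

#' Default pipeline run configuration
#'
#' @param seed Integer master seed.
#' @param ... Overrides: `k` (word length, one of 4/5/6), `tier`
#'   (db stringency), `subsample_length`, `world` (list of [world_config()]
#'   overrides), `ptu` / `plasmids` (lists of overrides for
#'   [generate_ptu_table()] / [generate_plasmid_set()]).
#' @return Named list.
#' @export
run_config <- function(seed = 1L, ...) {
  cfg <- list(seed = seed, k = 6L, tier = "all", subsample_length = 5000L,
              world = list(n_species = 4L, n_targets_per_species = 2L,
                           n_core_genes = 12L, n_noncore_genes = 6L,
                           n_plasmid_genes = 6L),
              ptu = list(), plasmids = list())
  over <- list(...)
  cfg[names(over)] <- over
  validate_run_config(cfg)
}

#' Validate a pipeline configuration
#'
#' Word lengths are restricted to k = 4, 5, 6 (longer recognition motifs are
#' too rare to analyse); the stringency tier must be one of the reference
#' tiers.
#'
#' @param config List as produced by [run_config()].
#' @return The config, invisibly, or an error.
#' @export
validate_run_config <- function(config) {
  if (!all(config$k %in% ALLOWED_K))
    stop("k must be in {4, 5, 6}; got ", paste(config$k, collapse = ", "),
         call. = FALSE)
  if (!config$tier %in% c("gold", "nonputative", "all"))
    stop("tier must be gold, nonputative or all", call. = FALSE)
  if (!is.numeric(config$subsample_length) || config$subsample_length <= config$k)
    stop("subsample_length must exceed k", call. = FALSE)
  invisible(config)
}

#' Load a pipeline configuration from a YAML file
#'
#' Fields mirror [run_config()]; unspecified fields take the defaults, and
#' the merged configuration is validated.
#'
#' @param path Path to a YAML file.
#' @return Validated config list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  seed <- if (is.null(raw$seed)) 1L else as.integer(raw$seed)
  raw$seed <- NULL
  do.call(run_config, c(list(seed = seed), raw))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full pipeline on a synthetic world
#'
#' Generates a world, plants its R-M systems as proteins in per-genome
#' proteomes, detects them against the generated reference database, builds
#' the presence matrix and taxonomic dictionary from the detected targets,
#' scores per-component avoidance for every species, and runs the plasmid
#' analyses (target density, PTU host-range model, MTase carriage). Writes
#' `calls.tsv`, `scores.tsv`, `densities.tsv`, `ptu_models.tsv`,
#' `mtase_carriage.tsv` and `manifest.json` under `out_dir`.
#'
#' @param config List from [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  validate_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  # -- simulate
  wcfg <- do.call(world_config,
                  c(list(seed = config$seed, k = config$k), config$world))
  world <- generate_world(wcfg)
  prot <- plant_world_proteomes(world, seed = config$seed)

  # -- detect
  hits <- find_enzyme_hits(prot$proteome, prot$db, config$tier)
  calls <- call_rm_systems(hits)
  write_tsv(calls, file.path(out_dir, "calls.tsv"))

  # -- dictionary (from detected targets, not the planted truth)
  genome_targets <- lapply(
    stats::setNames(nm = unique(prot$proteome$genome_id)),
    function(g) unique_genome_targets(calls, g))
  mat <- build_presence_matrix(genome_targets, world$genome_species,
                               config$k, species = world$taxonomy$species)
  dict <- build_dictionary(mat, world$taxonomy)
  write_presence_matrix(mat, file.path(out_dir, "presence_matrix.tsv"))

  # -- score
  scores <- do.call(rbind, lapply(world$taxonomy$species, function(sp) {
    prof <- component_avoidance_profile(world$genomes[[sp]], sp, dict,
                                        config$k, config$subsample_length,
                                        seed = config$seed)
    cbind(species = sp, prof, stringsAsFactors = FALSE)
  }))
  write_tsv(scores, file.path(out_dir, "scores.tsv"))

  # -- analyze
  densities <- do.call(rbind, lapply(world$taxonomy$species, function(sp) {
    genes <- world$genomes[[sp]]
    plaseq <- paste(genes$sequence[genes$component == "plasmid"], collapse = "")
    d <- target_density(plaseq, dict[[sp]]$species, id = paste0(sp, "_pl1"))
    cbind(species = sp, d, stringsAsFactors = FALSE)
  }))
  write_tsv(densities, file.path(out_dir, "densities.tsv"))

  ptu_tab <- do.call(generate_ptu_table,
                     c(list(seed = config$seed + 1L), config$ptu))
  ptu_fit <- fit_ptu_model(ptu_tab, level = "species")
  write_tsv(ptu_fit$coefficients, file.path(out_dir, "ptu_models.tsv"))

  plasmids <- do.call(generate_plasmid_set,
                      c(list(seed = config$seed + 2L), config$plasmids))
  carriage <- mtase_carriage_summary(plasmids)
  write_tsv(carriage$carriage, file.path(out_dir, "mtase_carriage.tsv"))

  manifest <- list(
    package = "rmavoid",
    version = as.character(utils::packageVersion("rmavoid")),
    seed = config$seed,
    config = config[c("k", "tier", "subsample_length")],
    outputs = as.list(tools::md5sum(list.files(out_dir, pattern = "\\.tsv$",
                                               full.names = TRUE))))
  names(manifest$outputs) <- basename(names(manifest$outputs))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(world = world, db = prot$db, proteome = prot$proteome,
                 hits = hits, calls = calls, presence_matrix = mat,
                 dictionary = dict, scores = scores, densities = densities,
                 ptu_fit = ptu_fit, carriage = carriage))
}

#' Plant a world's R-M systems as proteomes plus a reference database
#'
#' Each genome receives one complete MTase+REase pair (adjacent genes,
#' verbatim reference copies) per planted target of its species, so that
#' detection at any tier recovers exactly the planted target sets.
#'
#' @param world Output of [generate_world()].
#' @param seed Integer seed.
#' @return List with `db`, `proteome`, `truth` as in
#'   [generate_enzyme_db_and_proteomes()].
#' @export
plant_world_proteomes <- function(world, seed = 1L) {
  motifs <- sort(unique(unlist(world$species_targets)))
  if (length(motifs) == 0L)
    motifs <- "GAATTC"  # db must be non-empty even for a systemless world
  plants <- do.call(rbind, lapply(names(world$genome_species), function(g) {
    sp <- world$genome_species[[g]]
    tg <- world$species_targets[[sp]]
    if (length(tg) == 0L) return(NULL)
    data.frame(genome_id = g, system = match(tg, motifs),
               mtase_identity = 100, rease_identity = 100, gap = 1L,
               stringsAsFactors = FALSE)
  }))
  if (is.null(plants))
    plants <- data.frame(genome_id = names(world$genome_species)[1L],
                         system = integer(0L), mtase_identity = numeric(0L),
                         rease_identity = numeric(0L), gap = integer(0L))
  cfg <- list(seed = seed, motifs = motifs, plants = plants,
              tiers = rep("gold", length(motifs)))
  out <- generate_enzyme_db_and_proteomes(cfg)
  # genomes whose species has no targets still need (empty-ish) proteomes
  missing <- setdiff(names(world$genome_species),
                     unique(out$proteome$genome_id))
  if (length(missing)) {
    filler <- do.call(rbind, lapply(missing, function(g) data.frame(
      genome_id = g, replicon_id = "chr1", ordinal = 1L,
      protein_id = paste0(g, "_g001_fill"),
      sequence = random_protein(120L, seed + nchar(g)),
      stringsAsFactors = FALSE)))
    out$proteome <- rbind(out$proteome, filler)
  }
  out
}
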