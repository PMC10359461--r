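test_that("core classification applies the strict >99% single-copy rule", {
  genomes <- sprintf("g%03d", 1:100)
  pg <- rbind(
    data.frame(family = "famA", genome_id = genomes, count = 1L),          # 100/100
    data.frame(family = "famB", genome_id = genomes[1:99], count = 1L),    # 99/100
    data.frame(family = "famC", genome_id = genomes, count = 2L))          # multicopy
  cf <- classify_core_families(pg, genomes = genomes)
  expect_true(cf$core[cf$family == "famA"])    # 1.00 > 0.99
  expect_false(cf$core[cf$family == "famB"])   # 0.99 is not > 0.99
  expect_false(cf$core[cf$family == "famC"])
})

test_that("every gene gets exactly one component; plasmid replicons dominate", {
  genomes <- "g1"
  pg <- data.frame(family = c("famA", "famB"), genome_id = "g1", count = 1L)
  cf <- classify_core_families(pg, genomes = genomes)
  cf$core <- c(TRUE, FALSE)
  repmap <- data.frame(genome_id = "g1",
                       replicon_id = c("chr1", "pl1", "chr2"),
                       replicon_type = c("chromosome", "plasmid",
                                         "secondary_chromosome"))
  genes <- data.frame(genome_id = "g1",
                      replicon_id = c("chr1", "chr1", "pl1", "chr2"),
                      family = c("famA", "famB", "famA", "famB"))
  out <- assign_components(genes, cf, repmap)
  expect_identical(out$component, c("core", "non-core", "plasmid", "plasmid"))
  expect_identical(nrow(out), nrow(genes))
  expect_error(assign_components(transform(genes, genome_id = "gX"), cf, repmap),
               "gX")
})

test_that("target density matches direct counting and the 4^-k reference", {
  # a 4096 bp plasmid containing exactly one copy of a 6-bp target
  s <- paste0(strrep("C", 2000), "GAATTC", strrep("C", 2090))
  expect_identical(nchar(s), 4096L)
  d <- target_density(s, "GAATTC", id = "p1")
  expect_equal(d$mean_density, 4^-6)
  expect_identical(as.character(d$size_bin), "<10kb")
  expect_equal(target_density(s, "AAATTT")$mean_density, 0)
  expect_identical(target_density(s, character(0))$flag, "undefined")
  # Monte-Carlo: mean density over random plasmids near the 4^-k line
  dens <- vapply(1:20, function(i) {
    p <- generate_markov_sequence(2e4, 0, NULL, seed = 500 + i)
    target_density(p, enumerate_palindromes(6)[c(5, 20, 40)])$mean_density
  }, numeric(1))
  expect_lt(abs(mean(dens) - 4^-6) / 4^-6, 0.2)
})

test_that("density summaries suppress cells with five or fewer plasmids", {
  recs <- data.frame(
    species = rep(c("Sa", "Sb"), c(6, 5)),
    size_bin = "<10kb",
    mean_density = c(rep(1e-4, 6), rep(2e-4, 5)))
  out <- density_size_summary(recs)
  expect_identical(out$species, "Sa")  # Sb has exactly 5: suppressed
  expect_identical(out$n, 6L)
  expect_equal(out$median_density, 1e-4)
})

test_that("host-range classes map to an order-preserving numeric code", {
  expect_identical(host_range_numeric(c("I", "II", "III", "IV", "V", "VI")),
                   1:6)
  expect_true(is.na(host_range_numeric("unassigned")))
  expect_error(host_range_numeric("VII"), "unknown host-range")
})

test_that("PTU model recovers planted coefficients and flags degenerate designs", {
  tab <- generate_ptu_table(n = 200, beta_host = -0.5, beta_len = 0.8,
                            beta_n = 0, sigma = 0.1, seed = 11)
  fit <- fit_ptu_model(tab, level = "species")
  co <- fit$coefficients
  est <- function(term) co$estimate[co$term == term]
  se <- function(term) co$se[co$term == term]
  expect_lt(abs(est("host_range") - (-0.5)), 3 * se("host_range"))
  expect_lt(abs(est("log10_median_length") - 0.8), 3 * se("log10_median_length"))
  expect_lt(abs(est("n_plasmids") - 0), 3 * se("n_plasmids"))
  expect_gt(fit$r_squared, 0.9)
  # constant response: zero slopes, zero variance explained
  tab0 <- tab; tab0$response <- 1
  fit0 <- fit_ptu_model(tab0)
  expect_true(all(abs(fit0$coefficients$estimate[-1]) < 1e-10))
  expect_equal(fit0$r_squared, 0)
  # duplicated covariate: rank-deficiency error naming the collinear term
  tab_dup <- tab; tab_dup$n_plasmids <- tab_dup$host_range
  expect_error(fit_ptu_model(tab_dup), "collinear")
  expect_error(fit_ptu_model(tab[1:5, ]), "at least 10")
})

test_that("MTase carriage proportions and per-PTU densities are correct", {
  pls <- data.frame(
    plasmid_id = sprintf("p%d", 1:6),
    length = c(5e3, 5e3, 5e3, 5e3, 2e5, 2e5),
    ptu = c(rep("PTU1", 4), rep("PTU2", 2)),
    host_range = c(rep("I", 4), rep("VI", 2)),
    n_orphan_mtases = c(1L, 1L, 1L, 0L, 2L, 0L))
  out <- mtase_carriage_summary(pls)
  cell <- out$carriage[out$carriage$size_bin == "<10kb" &
                         out$carriage$host_range == "I", ]
  expect_equal(cell$proportion, 0.75)  # 3 of 4 small class-I plasmids
  expect_identical(cell$n_total, 4L)
  empty <- out$carriage[out$carriage$size_bin == ">100kb" &
                          out$carriage$host_range == "I", ]
  expect_identical(empty$flag, "empty_bin")
  d2 <- out$ptu_density[out$ptu_density$ptu == "PTU2", ]
  expect_equal(d2$mtases_per_kb, 2 / 400)
  # all-zero carriage gives all-zero proportions where defined
  pls0 <- transform(pls, n_orphan_mtases = 0L)
  out0 <- mtase_carriage_summary(pls0)
  expect_true(all(out0$carriage$proportion[out0$carriage$flag == "ok"] == 0))
})

test_that("planted carriage effects (size, host range) are recovered in sign", {
  ok <- 0
  for (i in 1:5) {
    pls <- generate_plasmid_set(n = 400, seed = 40 + i)
    fit <- stats::glm(I(n_orphan_mtases > 0) ~ log10(length) + host_range_numeric,
                      family = stats::binomial(), data = pls)
    co <- stats::coef(fit)
    ok <- ok + (co[["log10(length)"]] > 0 && co[["host_range_numeric"]] > 0)
  }
  expect_gte(ok, 4)
})

test_that("component profiles: exclusion, undefined sets, and level-set equality", {
  tx <- toy_taxonomy()
  m <- matrix(0L, 4, 2, dimnames = list(tx$species, c("AAATTT", "CCCGGG")))
  m["Sa", "AAATTT"] <- 1L
  m["Sd", "CCCGGG"] <- 1L
  dict <- build_dictionary(m, tx)
  genes <- data.frame(
    component = rep(c("core", "non-core", "plasmid"), each = 3),
    sequence = vapply(1:9, function(i) random_dna(2000, 600 + i), character(1)))
  prof <- component_avoidance_profile(genes, "Sa", dict, 6,
                                      subsample_length = 5000, seed = 2)
  expect_identical(nrow(prof), 21L)  # 3 components x 7 levels
  # Sa shares genus/family/... sets with no other targeted species until kingdom
  core <- prof[prof$component == "core", ]
  same <- core[core$level %in% c("species", "genus", "family"), "median_z"]
  expect_true(all(same == same[1]))  # identical sets -> identical scores
  # kingdom adds Sd's target, so the set differs
  expect_identical(core$n_targets[core$level == "kingdom"], 2L)
  # insufficient sequence in every component: all excluded
  prof2 <- component_avoidance_profile(genes, "Sa", dict, 6,
                                       subsample_length = 10000, seed = 2)
  expect_true(all(prof2$flag == "insufficient_sequence"))
  # a species with no systems anywhere in its lineage: undefined at species level
  prof3 <- component_avoidance_profile(genes, "Sb", dict, 6,
                                       subsample_length = 5000, seed = 2)
  expect_identical(unique(prof3$flag[prof3$level == "species"]), "undefined")
})

test_that("plasmid genes engineered to avoid within-species targets score below core", {
  wins <- 0
  for (i in 1:10) {
    w <- generate_world(world_config(seed = 900 + i, n_species = 4,
                                     n_core_genes = 12, n_noncore_genes = 4,
                                     n_plasmid_genes = 12, gene_length = 1000,
                                     f_plasmid = 0.9))
    sp <- w$taxonomy$species[1]
    prof <- component_avoidance_profile(w$genomes[[sp]], sp, w$dictionary, 6,
                                        subsample_length = 10000,
                                        seed = 900 + i)
    z_pl <- prof$median_z[prof$component == "plasmid" & prof$level == "species"]
    z_co <- prof$median_z[prof$component == "core" & prof$level == "species"]
    wins <- wins + (z_pl < z_co)
  }
  expect_gte(wins, 8)
})
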