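test_that("Markov sequences are reproducible and respect composition", {
  s1 <- generate_markov_sequence(4096, 0, NULL, seed = 1)
  s2 <- generate_markov_sequence(4096, 0, NULL, seed = 1)
  expect_identical(s1, s2)
  expect_identical(nchar(s1), 4096L)
  expect_false(identical(s1, generate_markov_sequence(4096, 0, NULL, seed = 2)))
  # uniform order 0: pooled base frequencies within 3 sigma of 1/4
  pooled <- unlist(lapply(1:5, function(i)
    strsplit(generate_markov_sequence(4096, 0, NULL, seed = i), "")[[1]]))
  freq <- table(factor(pooled, levels = c("A", "C", "G", "T"))) / length(pooled)
  sigma <- sqrt(0.25 * 0.75 / length(pooled))
  expect_true(all(abs(freq - 0.25) < 3 * sigma))
  # skewed composition shows up in base frequencies
  sk <- generate_markov_sequence(5000, 0, c(0.7, 0.1, 0.1, 0.1), seed = 3)
  expect_gt(mean(strsplit(sk, "")[[1]] == "A"), 0.6)
  expect_error(generate_markov_sequence(100, 0, c(0.5, 0.5, 0.5, 0.5)),
               "summing to 1")
})

test_that("order-1 chains with planted AA-rich transitions enrich AA dinucleotides", {
  trans <- matrix(0.25, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                              c("A", "C", "G", "T")))
  trans["A", ] <- c(0.7, 0.1, 0.1, 0.1)
  s <- generate_markov_sequence(2e4, 1, trans, seed = 4)
  # stationary distribution of this chain: solve pi = pi P
  pi_st <- Re(eigen(t(trans))$vectors[, 1]); pi_st <- pi_st / sum(pi_st)
  expected_aa <- pi_st[1] * 0.7           # P(A) * P(A|A)
  uniform_aa <- 1 / 16
  got_aa <- count_overlapping(s, "AA") / (2e4 - 1)
  expect_gt(got_aa, uniform_aa)
  expect_lt(abs(got_aa - expected_aa), 0.02)
  expect_error(generate_markov_sequence(100, 1, matrix(1, 2, 2)), "4 x 4")
})

test_that("depletion removes the requested fraction without side effects", {
  s <- generate_markov_sequence(5e4, 0, NULL, seed = 10)
  w <- "GGTACC"
  expect_identical(deplete_word(s, w, 0, seed = 1), s)
  d1 <- deplete_word(s, w, 1, seed = 1)
  expect_identical(count_overlapping(d1, w), 0L)
  expect_identical(nchar(d1), nchar(s))
  # exactly half of 20 non-overlapping occurrences survive f = 0.5
  background <- strrep("C", 30)
  planted <- paste(rep(paste0(background, "GAATTC"), 20), collapse = "")
  expect_identical(count_overlapping(planted, "GAATTC"), 20L)
  half <- deplete_word(planted, "GAATTC", 0.5, seed = 6)
  expect_identical(count_overlapping(half, "GAATTC"), 10L)
  expect_identical(nchar(half), nchar(planted))
})

test_that("depletion never increases a word's count and preserves length", {
  for (i in 1:10) {
    s <- generate_markov_sequence(3000, 0, NULL, seed = 200 + i)
    w <- random_word(4, i)
    n0 <- count_overlapping(s, w)
    for (f in c(0.3, 0.7, 1)) {
      d <- deplete_word(s, w, f, seed = i)
      expect_lte(count_overlapping(d, w), n0)
      expect_identical(nchar(d), nchar(s))
    }
  }
})

test_that("depleted-occurrence subsets are nested in f for a fixed seed", {
  s <- generate_markov_sequence(5e4, 0, NULL, seed = 33)
  w <- "CCATGG"
  counts <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(f)
    count_overlapping(deplete_word(s, w, f, seed = 5), w), integer(1))
  expect_true(all(diff(counts) <= 0))
  expect_identical(counts[5], 0L)
})

test_that("identity-targeted mutation reports realised identity at or below target", {
  p <- random_protein(120, 7)
  for (target in c(80, 55, 50)) {
    m <- mutate_protein_to_identity(p, target, seed = target)
    expect_lte(m$identity, target)
    expect_gt(m$identity, target - 5)  # single substitutions: small overshoot
    expect_equal(percent_identity(p, m$sequence), m$identity)
  }
  expect_identical(mutate_protein_to_identity(p, 100, 1)$sequence, p)
})

test_that("generated taxonomies are nested and reproducible", {
  tx <- generate_taxonomy(12, seed = 5)
  expect_identical(tx, generate_taxonomy(12, seed = 5))
  expect_identical(nrow(tx), 12L)
  rmavoid:::validate_taxonomy(tx)
  # species sharing a genus share all higher ranks
  for (g in unique(tx$genus)) {
    sub <- tx[tx$genus == g, ]
    for (r in c("family", "order", "class", "phylum"))
      expect_identical(length(unique(sub[[r]])), 1L)
  }
})

test_that("planted enzyme worlds carry a truth table consistent with their plants", {
  out <- generate_enzyme_db_and_proteomes(list(seed = 2))
  expect_identical(nrow(out$truth), 3L)
  expect_true(out$truth$system_detectable[1])   # complete system at 100%
  expect_true(out$truth$orphan_mtase[2])        # MTase-only plant
  expect_true(out$truth$orphan_mtase[3])        # REase outside the window
  expect_false(out$truth$system_detectable[3])
  # ordinals are unique and consecutive per replicon
  ords <- out$proteome$ordinal[out$proteome$replicon_id == "chr1"]
  expect_identical(sort(ords), seq_along(ords))
})

test_that("PTU and plasmid generators embed their planted parameters", {
  tab <- generate_ptu_table(n = 50, seed = 3)
  expect_identical(nrow(tab), 50L)
  expect_identical(attr(tab, "planted")[["host"]], -0.5)
  expect_identical(tab, generate_ptu_table(n = 50, seed = 3))
  pls <- generate_plasmid_set(n = 100, seed = 3)
  expect_identical(nrow(pls), 100L)
  expect_true(all(pls$n_orphan_mtases %in% 0:1))
  expect_true(all(pls$host_range %in% c("I", "II", "III", "IV", "V", "VI")))
})

test_that("a world without R-M systems yields an empty presence matrix", {
  w <- generate_world(world_config(seed = 2, n_species = 3,
                                   n_targets_per_species = 0,
                                   n_core_genes = 2, n_noncore_genes = 1,
                                   n_plasmid_genes = 1, gene_length = 300))
  expect_identical(ncol(w$presence_matrix), 0L)
  expect_identical(nrow(w$presence_matrix), 3L)
  expect_length(w$dictionary[[1]]$kingdom, 0L)
})

test_that("worlds are pure functions of their seed", {
  cfg <- world_config(seed = 9, n_species = 3, n_core_genes = 2,
                      n_noncore_genes = 1, n_plasmid_genes = 2,
                      gene_length = 400)
  w1 <- generate_world(cfg)
  w2 <- generate_world(cfg)
  expect_identical(w1$genomes, w2$genomes)
  expect_identical(w1$presence_matrix, w2$presence_matrix)
})
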