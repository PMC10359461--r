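db_small <- function(seed = 1) {
  generate_enzyme_db_and_proteomes(list(seed = seed))$db
}

test_that("percent identity: global alignment, gaps in the denominator, symmetric", {
  p <- random_protein(100, 1)
  expect_equal(percent_identity(p, p), 100)
  expect_equal(percent_identity("AAAA", "AAAA"), 100)
  expect_equal(percent_identity("AAAA", "AAAC"), 75)
  # X never counts as a match even against X
  expect_lt(percent_identity("AXAA", "AXAA"), 100)
  set.seed(2)
  for (i in 1:10) {
    a <- random_protein(60, i)
    b <- random_protein(60, i + 50)
    expect_equal(percent_identity(a, b), percent_identity(b, a))
  }
  expect_error(percent_identity("", "AAA"), "non-empty")
})

test_that("motif normalisation collapses a motif with its reverse complement", {
  expect_identical(normalise_motif("GAATTC"), "GAATTC")
  expect_identical(normalise_motif("gaattc"), "GAATTC")
  # TTCGAA's reverse complement also TTCGAA (palindrome); unrelated pair:
  expect_identical(normalise_motif("TTAACC"), normalise_motif("GGTTAA"))
  expect_identical(normalise_motif("GANTC"), "GANTC")
})

test_that("hits require the inclusive class identity thresholds", {
  out <- generate_enzyme_db_and_proteomes(list(
    seed = 5, plants = data.frame(
      genome_id = "G1", system = 1:2,
      mtase_identity = c(100, 53), rease_identity = c(100, 48),
      gap = c(1L, 1L))))
  hits <- find_enzyme_hits(out$proteome, out$db, "all")
  # system 1 planted verbatim: both hits at 100
  expect_true(any(hits$class == "MTase" & hits$identity == 100))
  expect_true(any(hits$class == "REase" & hits$identity == 100))
  # system 2 mutated below both thresholds: no hits from it
  tr2 <- out$truth[out$truth$system == 2, ]
  expect_lt(tr2$mtase_identity, 55)
  expect_lt(tr2$rease_identity, 50)
  expect_false(any(hits$ordinal %in% c(tr2$mtase_ordinal, tr2$rease_ordinal)))
})

test_that("tier filtering is monotone: gold within nonputative within all", {
  plants <- data.frame(genome_id = "G1", system = 1:6,
                       mtase_identity = 100, rease_identity = 100, gap = 1L)
  out <- generate_enzyme_db_and_proteomes(list(seed = 9, plants = plants))
  h_gold <- find_enzyme_hits(out$proteome, out$db, "gold")
  h_nonp <- find_enzyme_hits(out$proteome, out$db, "nonputative")
  h_all <- find_enzyme_hits(out$proteome, out$db, "all")
  key <- function(h) paste(h$protein_id, h$class)
  expect_true(all(key(h_gold) %in% key(h_nonp)))
  expect_true(all(key(h_nonp) %in% key(h_all)))
  # putative-tier enzymes are only found in "all" mode
  expect_lt(nrow(h_gold), nrow(h_nonp))
  expect_lt(nrow(h_nonp), nrow(h_all))
})

test_that("system calls require shared target within the 4-gene window", {
  mk_hits <- function(re_ordinal, re_motif = "GAATTC") {
    data.frame(genome_id = "G", replicon_id = "chr",
               ordinal = c(10L, re_ordinal),
               protein_id = c("m", "r"), class = c("MTase", "REase"),
               enzyme_id = c("M.X", "R.X"), identity = c(100, 100),
               motif = c("GAATTC", re_motif),
               motif_norm = normalise_motif(c("GAATTC", re_motif)),
               stringsAsFactors = FALSE)
  }
  expect_identical(nrow(call_rm_systems(mk_hits(14L))), 1L)  # 3 intermediates
  expect_identical(call_rm_systems(mk_hits(14L))$n_intermediate, 3L)
  expect_identical(nrow(call_rm_systems(mk_hits(15L))), 0L)  # distance 5
  expect_identical(nrow(call_rm_systems(mk_hits(11L, "GGATCC"))), 0L)
})

test_that("overlapping systems are all reported and targets deduplicated", {
  # two MTases flanking one REase, all with the same target
  hits <- data.frame(genome_id = "G", replicon_id = "chr",
                     ordinal = c(1L, 3L, 5L),
                     protein_id = c("m1", "r1", "m2"),
                     class = c("MTase", "REase", "MTase"),
                     enzyme_id = c("M.A", "R.A", "M.B"),
                     identity = 100, motif = "GAATTC",
                     motif_norm = "GAATTC", stringsAsFactors = FALSE)
  calls <- call_rm_systems(hits)
  expect_identical(nrow(calls), 2L)
  expect_identical(unique_genome_targets(calls, "G"), "GAATTC")
  expect_identical(unique_genome_targets(calls[0, ]), character(0))
})

test_that("orphan MTases are those without a cognate REase within the window", {
  out <- generate_enzyme_db_and_proteomes(list(
    seed = 3, plants = data.frame(
      genome_id = "G1", system = 1:3,
      mtase_identity = 100, rease_identity = c(100, NA, 100),
      gap = c(1L, NA, 6L))))
  orphans <- find_orphan_mtases(out$proteome, out$db, "all")
  truth_orphans <- out$truth[out$truth$orphan_mtase, ]
  expect_identical(sort(orphans$ordinal), sort(truth_orphans$mtase_ordinal))
  # the complete system's MTase is not an orphan
  expect_false(out$truth$mtase_ordinal[1] %in% orphans$ordinal)
  expect_identical(nrow(orphans), 2L)
})

test_that("noiseless planted systems are recovered with perfect precision and recall", {
  plants <- data.frame(genome_id = rep(c("G1", "G2"), each = 3),
                       system = c(1:3, 4:6),
                       mtase_identity = 100, rease_identity = 100,
                       gap = rep(c(1L, 2L, 4L), 2))
  out <- generate_enzyme_db_and_proteomes(list(seed = 21, plants = plants))
  hits <- find_enzyme_hits(out$proteome, out$db, "all")
  calls <- call_rm_systems(hits)
  truth <- out$truth
  called <- paste(calls$genome_id, calls$motif)
  planted <- paste(truth$genome_id, truth$motif_norm)
  expect_setequal(called, planted)         # recall and precision both 1
  expect_identical(nrow(calls), nrow(truth))
  for (g in c("G1", "G2"))
    expect_setequal(unique_genome_targets(calls, g),
                    sort(truth$motif_norm[truth$genome_id == g]))
})

test_that("threshold boundary: hit iff realised identity meets the class minimum", {
  for (rep in 1:5) {
    plants <- data.frame(genome_id = "G1", system = 1:4,
                         mtase_identity = c(58, 53, 100, 100),
                         rease_identity = c(100, 100, 52, 47),
                         gap = 1L)
    out <- generate_enzyme_db_and_proteomes(list(seed = 100 + rep,
                                                 plants = plants))
    hits <- find_enzyme_hits(out$proteome, out$db, "all")
    for (i in seq_len(nrow(out$truth))) {
      tr <- out$truth[i, ]
      expect_identical(any(hits$class == "MTase" & hits$ordinal == tr$mtase_ordinal),
                       tr$mtase_identity >= 55)
      expect_identical(any(hits$class == "REase" & hits$ordinal == tr$rease_ordinal),
                       tr$rease_identity >= 50)
    }
  }
})

test_that("fused-enzyme reference entries are rejected with a warning", {
  db <- db_small(4)
  db$class[1] <- "IIG"
  proteome <- data.frame(genome_id = "G", replicon_id = "c", ordinal = 1L,
                         protein_id = "p", sequence = random_protein(80, 1),
                         stringsAsFactors = FALSE)
  expect_warning(find_enzyme_hits(proteome, db, "all"), "separate")
  expect_warning(find_enzyme_hits(proteome, db[db$tier == "none", ], "all"),
                 "empty reference")
})
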