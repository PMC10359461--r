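---
title: "Scoring restriction-target avoidance with maximal Markov models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring restriction-target avoidance with maximal Markov models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rmavoid)
```

## The problem

Type II restriction–modification (R-M) systems are the most abundant
bacterial defence systems. Each consists of a restriction endonuclease
(REase) that cuts DNA at a short recognition target — usually a 4–8 bp
palindrome — and a methyltransferase (MTase) that protects the host's own
copies of that target. Incoming DNA, such as a transferred plasmid, lacks
the protective methylation and is cut. This puts mobile DNA under selection
to *lose* the targets of the R-M systems it encounters, and the strength of
that footprint should track how often a target is encountered: targets of
systems carried by the plasmid's own species should be avoided most, those
seen only in distant taxa least.

`rmavoid` implements that analysis end to end: detecting Type II systems in
annotated proteomes, assembling which targets occur where across a taxonomy,
scoring statistical avoidance of target words, and relating avoidance to
pangenome component (core / non-core / plasmid genes), plasmid size, and
plasmid host range. Everything runs on seeded synthetic data with planted
ground truth, so every step of the pipeline is testable against what was
planted.

## The exceptionality score

Counting a word's occurrences is not enough: a GC-rich genome contains fewer
AT-rich words for reasons that have nothing to do with restriction. The
package therefore scores each word $W$ of length $k$ against the *maximal
Markov model* of order $m = k - 2$, which conditions on the observed counts
of all sub-words up to length $k-1$. Writing $N(\cdot)$ for overlapping
occurrence counts, $W^-$ and $^-W$ for the $(k-1)$-prefix and suffix, and
$^-W^-$ for the $(k-2)$ middle word:

$$\hat E = \frac{N(W^-)\,N({}^-W)}{N({}^-W^-)}, \qquad
\hat V = \hat E\left(1 - \frac{N(W^-)}{N({}^-W^-)}\right)
              \left(1 - \frac{N({}^-W)}{N({}^-W^-)}\right), \qquad
Z = \frac{N(W) - \hat E}{\sqrt{\hat V}}.$$

Negative $Z$ indicates avoidance; positive $Z$ over-representation. The
maximal model is the strictest null available from word counts: a deficit of
$W$ under it signals selection against the word itself rather than against
any of its sub-words. The order restriction $m = k-2 \ge 1$ means words of
length $< 3$ are not scorable, and the package refuses them.

```{r}
z_score("AATAAT", "AAT")
```

Two degenerate cases need conventions:

* **Never observed, never expected** ($N = 0$, $\hat E = 0$): the score is
  *defined* as zero. A word cannot be called avoided if the sequence
  composition never predicted it in the first place.
* **Zero variance with non-trivial counts** (a sub-word ratio of exactly 1):
  flagged `degenerate` and excluded from group summaries rather than mapped
  to $\pm\infty$.

A consequence of the zero/zero rule worth knowing: in short sequences where
a word's expected count is $\ll 1$, complete absence of the word often comes
with absent sub-words too, and the score collapses to 0 rather than going
negative. Avoidance comparisons therefore need sequence lengths where
$\hat E \gtrsim 2$ per word — for 6-mers that means roughly $\ge 10$ kb.
This is why components are compared after subsampling to fixed lengths of at
least 10 kb in the shipped analyses, and why very short components are
excluded rather than scored.

Sub-word counts are taken over the full scored sequence rather than aligned
windows; the boundary difference is $O(1)$ and the calibration test below
confirms it is negligible at the lengths used.

### Calibration and validation

Three independent checks back the implementation, all in the test suite:

* an exact-agreement oracle — a brute-force implementation of the same
  formulas from naive substring counts matches $\hat E$, $\hat V$, $Z$ to
  $10^{-9}$ on hundreds of random small cases;
* a Monte-Carlo calibration — on uniform-random 100 kb sequences, $Z$ over
  all 4096 6-mers is close to standard normal (|mean| < 0.1, SD within
  [0.85, 1.15]);
* a depletion response — removing a fraction $f$ of a palindrome's
  occurrences from a Markov sequence drives its $Z$ strictly downward over
  $f \in \{0, 0.25, 0.5, 0.75, 1\}$.

## Detecting R-M systems

Detection follows the protein-similarity logic of target prediction from a
curated enzyme reference: a proteome gene is a candidate MTase or REase if
its global-alignment percent identity to a reference enzyme of that class
reaches the class threshold — 55% for MTases, 50% for REases, inclusive —
and it inherits the reference enzyme's recognition motif. Identity is
computed from a Needleman–Wunsch alignment (BLOSUM62, gap open 10, extend
0.5) as matches over all alignment columns, gaps included; `X` never counts
as a match. A *system call* is an MTase and REase pair on the same replicon
with the same normalised target within 4 genes (at most 3 intermediate
genes). MTase hits with no such partner are *orphan MTases* — of interest
because an orphan MTase protects a plasmid from restriction without any
cutting activity.

Design choices made here, where the underlying convention was genuinely
open:

* "Shared target" means string identity after normalisation: uppercase, and
  a motif collapsed with its reverse complement to the lexicographically
  smaller of the pair. This is conservative — degenerate motifs whose
  expansions merely overlap do not pair.
* Threshold comparisons are inclusive ($\ge$), reading the published
  defaults as minima.
* Reference entries that are not cleanly MTase or REase (fused
  REase–MTase enzymes) are dropped with a warning; only systems with
  separate enzymes are in scope, since target prediction for fused enzymes
  is unreliable.
* Every gene is compared to the full (desk-scale) reference directly; a
  pre-screening step for large references is a performance optimisation,
  not part of the detection semantics.
* Pairing requires a shared normalised motif, not a shared reference
  system: any MTase/REase hit pair with the same target within the window
  is a call, and one enzyme may appear in several overlapping calls.

## The taxonomic target dictionary

Detected targets are aggregated per species into a binary presence/absence
matrix over unambiguous $k$-mers, one matrix per $k \in \{4, 5, 6\}$
(longer motifs are too rare to analyse). Degenerate motifs are expanded —
`GANTC` contributes four 5-mers, each weighted equally — and only presence
is recorded, never prevalence. From the matrix and a seven-rank taxonomy the
*taxonomic dictionary* gives, for every species, the union of targets
observed at each rank: its own row at species level, the union over
congeners at genus level, and so on up to the kingdom level, which is the
union over the whole dataset. These sets are nested by construction, and a
property test asserts the nesting over randomised taxonomies.

```{r}
tx <- generate_taxonomy(6, seed = 1)
m <- generate_random_presence(tx$species, enumerate_palindromes(6)[1:12],
                              p = 0.2, seed = 2)
vapply(build_dictionary(m, tx)[[1]], length, integer(1))
```

## Downstream analyses

**Pangenome components.** A gene family is *core* iff strictly more than
99% of genomes carry exactly one copy — relaxed from a strict all-genomes
rule so that one bad assembly cannot eject a family from the core. Genes on
plasmids and on secondary chromosomes are component `plasmid` regardless of
family (secondary chromosomes behave like megaplasmids for this purpose);
remaining chromosomal genes are core or non-core by family. Components are
subsampled to a fixed length (canonical lengths 2.5–100 kb) before scoring
so that statistical power is equal across components.

**Density vs size.** The mean per-base density of a target set in a plasmid
is compared against the random-sequence reference $4^{-k}$; per-species
summaries are medians over plasmids within size bins
($<10$, $10$–$20$, $20$–$50$, $50$–$100$, $>100$ kb — chosen to expose the
characteristic bimodal plasmid size distribution and its ~20 kb trough),
suppressing species/bin cells with five or fewer plasmids.

**Host range models.** Plasmid taxonomic units (PTUs) carry a host-range
class I–VI, coded 1–6 (unassigned plasmids excluded). Mean exceptionality
per PTU is modelled by ordinary least squares on numeric host range, log10
median plasmid length, and member count, one fit per dictionary level.
Rank-deficient designs are an error naming the collinear terms; a constant
response fits with zero slopes and $R^2 = 0$. (A phylogenetically
controlled mixed model would be the stricter analysis for real data across
species; the package emits the per-isolate component tables such a model
would consume, and keeps plain OLS as its own summary.)

**MTase carriage.** Orphan-MTase carriage is tabulated by size bin and
host-range class, plus a per-PTU orphan density in MTases per kb.

## The synthetic world

The generators produce every input the pipeline consumes, as pure functions
of a seed:

* **Markov sequences** of any order (order 0 and 1 are used throughout),
  with validated composition parameters.
* **Word depletion**: a fraction $f$ of a word's occurrences — chosen
  uniformly, nested in $f$ for a fixed seed — are each destroyed by one
  substitution of the word's middle base, with the replacement chosen so no
  new occurrence appears; $f = 1$ guarantees none remain. Length is always
  preserved.
* **Proteomes with planted systems**: reference enzymes are random proteins
  (120 residues by default); planted copies are mutated one substitution at
  a time until the *measured* alignment identity first falls to the target,
  and the realised identity is recorded in the truth table — tests condition
  on realised, never nominal, identity, which decouples them from the
  mutation path.
* **Worlds**: 8 species in a balanced pairwise-nested taxonomy, 3
  palindromic 6-bp targets per species drawn from the 64-palindrome panel,
  1 kb genes (30 core / 15 non-core / 15 plasmid by default), and plasmid
  genes depleted of within-species targets at $f = 0.8$ — a strong but not
  total footprint, representing long-term selection. Engineered gradient
  plasmids use depletion fractions decreasing with the rank at which a
  target first enters the species' dictionary (0.95 at species down to 0.1
  at kingdom).
* **PTU and plasmid tables** with planted regression effects
  ($\beta_{host} = -0.5$, $\beta_{len} = +0.8$, $\beta_n = 0$, $\sigma =
  0.1$) and a logistic orphan-MTase carriage model increasing with size and
  host range.

What the generator does *not* emulate is worth stating: real gene content
and codon structure, phylogenetic correlation of composition between related
species, amelioration of transferred DNA, and defence systems other than
Type II R-M. Passing recovery tests therefore show that the pipeline's
statistics recover planted signals of the stated form — not that real
pangenomes contain such signals.

## Problem sizes and numerical conventions

The shipped analyses and tests use worlds of 3–8 species, genes of 0.3–1
kb, scored sequences of 5–100 kb, calibration over 200 sequences of 100 kb,
and 10-seed replication for stochastic recovery checks. Counting is
forward-strand only (palindromes are strand-symmetric, which covers the
palindrome analyses; a both-strands flag sums a word with its reverse
complement for non-palindromic targets). Windows containing a non-ACGT base
never match at any word length. Internally coordinates are 0-based
half-open; reported positions are 1-based. Ties in best-hit selection break
to the lexicographically smallest enzyme id, making detection deterministic.

Species-level summaries compute per-genome scores and then average, rather
than pooling sequence before scoring; pooling remains available by
concatenating sequences upstream of `score_target_group()`.

## Known limitations

* The Gaussian approximation behind $Z$ degrades when $\hat E$ is small;
  the zero/zero and degenerate conventions handle the extremes, but scores
  at $\hat E < 1$ are noisy and group medians over few targets inherit that
  noise.
* Detection assumes the ordered-proteome abstraction (ordinal gene
  positions per replicon); it does not model strand, intergenic distance in
  bases, or pseudogenes.
* The OLS host-range model treats PTUs as independent; real PTUs share
  phylogenetic history.
* Only Type II systems with separate MTase and REase are detected; Type I,
  III, IV and fused Type IIG systems are out of scope.
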