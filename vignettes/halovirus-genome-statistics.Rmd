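---
title: "Motif avoidance, terminal repeats and CxxC censuses in halovirus genomes"
author: "halomotif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif avoidance, terminal repeats and CxxC censuses in halovirus genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(halomotif)
```

## The biological problem

The HF1 group of haloarchaeal myoviruses — lytic, tailed viruses of
hypersaline lakes — carry linear dsDNA genomes of roughly 69–78 kb at
55–57% G+C, bounded by long terminal direct repeats (TDRs) of a few hundred
base pairs. Their hosts deploy sequence-specific defenses, most prominently
restriction–modification (R–M) systems recognizing short reverse-complement
palindromes such as GATC (Dam-type methylation) and CTAG (Zim-type). A
virus genome that simply lacks those words is invisible to the
corresponding endonuclease, and the HF1-group genomes show exactly this
signature: some palindromes are entirely absent, others strongly depleted.
The same genomes also encode a conspicuous number of small proteins with
CxxC motifs — the spacing signature of zinc-finger interaction domains —
and, being closely related, are natural material for whole-genome identity
comparison. `halomotif` implements each of these measurements, plus a
simulator that generates genomes with all of the same statistical
structure, so that every claim the analyses make can be tested against
planted ground truth without any download.

## The avoidance statistic

For a word $w$ of length $k$ in a genome with $N_j$ valid overlapping
$j$-windows, let $f(\cdot)$ denote observed frequencies (count divided by
window count at the appropriate length). The package scores avoidance as an
observed/expected odds ratio under the **maximal-order Markov null**:

$$
E(w) \;=\; N_k \,
\frac{f\!\left(w_{1..k-1}\right)\, f\!\left(w_{2..k}\right)}
     {f\!\left(w_{2..k-1}\right)},
\qquad
\text{odds}(w) \;=\; \frac{\mathrm{obs}(w)}{E(w)} .
$$

This is the standard relative-abundance measure for oligonucleotide bias
studies: it conditions on the genome's own $(k{-}1)$-mer composition, so
that codon usage, G+C and shorter-range structure are absorbed by the null,
and what remains is bias specific to the full word. On Markov-generated
text of any order up to $k-2$ the odds concentrate near 1 (the calibration
tests verify the mean over all sixteen palindromic 4-mers stays within
[0.95, 1.05] on order-0, -1 and -2 simulations); values well below 1
indicate avoidance. A zero-order null ($E = N_k \prod_i f(w_i)$) is
available for comparison. Which particular Markov order sits behind
published "odds" figures is often unstated; the maximal-order form is the
default here precisely because it is the convention that makes near-1
values the neutral expectation, and both nulls are exposed so users can
quantify the difference (for typical 75 kb genomes it is within a few
hundredths).

Conventions that matter:

* **Forward-strand counting.** Every motif in the avoidance panels is a
  reverse-complement palindrome, for which forward counts already cover
  both strands. For non-palindromic motifs, `count_ambiguous_motif()` has a
  `both_strands` flag that adds reverse-strand matches (self-complementary
  motifs are counted once per duplex site).
* **N handling.** Windows containing `N` are skipped, never imputed. The
  deposited HF1-group genomes are N-free, so this only affects user data.
* **Classification.** `absent` iff the observed count is 0;
  `under_represented` when odds < 0.78 (the conventional cut for tetramer
  relative abundance, configurable); `normal` otherwise. Report layers
  print odds to two decimals and render normal cells as `"."`.
* **Terminal repeats are counted twice.** Counts are taken over the full
  deposited sequence, with no masking of the repeated terminus — the same
  convention under which published counts on deposited sequences arise.
* **Topology.** For circular records (a provirus circle before
  linearization) the $k-1$ wrap-around windows are included, so circles
  and linear virions are both well defined.

The census over all $4^{k/2}$ palindromes of length $k$ applies a
**sub-motif exclusion rule**: when a shorter motif (say CTAG) is itself
absent, every longer word containing it is trivially absent too, so such
candidates are excluded before asking which $k$-mers are independently
absent from every genome. Exclusion is a plain substring test against the
user-supplied list.

## Terminal direct repeats

`find_tdr()` returns the largest $L \le n/2$ such that the Hamming distance
between the first and last $L$ bases is at most `max_mismatch`. The default
is exact matching (`max_mismatch = 0`), the situation in finished genomes
where the two repeat copies are identical by construction of the assembly;
the mismatch tolerance exists for draft sequences. The $n/2$ cap prevents
the two copies from overlapping; lengths below `min_len` (default 20)
report as "no TDR". With mismatches allowed, several $L$ can satisfy the
bound and the largest is returned — this makes the reported length
non-decreasing in `max_mismatch`, a property the tests assert. The
provirus path is the mirror image: `linearize_provirus()` excises the
segment between the attachment sites and rotates it so a chosen terminus
offset becomes position zero. The terminus offset is an explicit argument
rather than something the package infers, because terminus placement for
an integrated element is a judgment call best left to the analyst.

## CxxC census

`scan_cxxc()` reports every position $i$ with cysteines at $i$ and $i+3$
(overlaps included); alternative spacings are available behind a flag but
exactly C-x-x-C is the default motif. The census counts *proteins* with at
least one motif — not motif totals — and classifies those shorter than 100
amino acids (strictly) as micro-proteins. Proteins are taken from the
`/translation` qualifier when present, since that is what curated
annotation provides; otherwise the CDS span is translated with genetic
code table 11 and the stop trimmed. CDS that can be neither looked up nor
translated are skipped, warned about, and tallied.

## Pairwise identity

`pairwise_identity()` approximates percent-identical-nucleotides-after-
alignment without running a full multiple aligner:

1. exact shared $k$-mers ($k = 14$ by default) on both strands are merged
   along diagonals and extended without gaps under an X-drop rule
   (match +1, mismatch −2, drop 20), discarding anchors under 30 bp;
2. anchors are chained by a weighted longest-increasing-subsequence
   (weight = match count, overlaps trimmed, strand chosen by total chain
   weight);
3. inter-anchor gaps up to 5,000 bp are closed by dynamic-programming
   global alignment (match 2, mismatch −3, gap open 5, extend 2); larger
   or one-sided gaps contribute $\max(g_a, g_b)$ unaligned columns;
   terminal overhangs follow the same rule;
4. identity = identical columns / all columns, gap columns included.

The gap cap bounds worst-case alignment work on 75 kb genomes to desk
scale; seeds occurring more than 64 times in the subject are masked, the
usual guard against low-complexity blow-up. Identical sequences score
exactly 100.0; a pair at substitution rate $r$ scores $\approx 100(1-r)$,
and tests verify agreement within one point against a full
dynamic-programming oracle on short pairs, symmetry within half a point,
and monotone degradation in $r$. Because terminal-gap and indel-column
conventions differ between aligners, comparisons against published
percentages should allow a ±2-point tolerance — the package documents
and uses that policy rather than pretending column conventions are
universal.

## The synthetic-genome generator

`generate_genome()` builds genomes with the statistical structure the
analyses assume:

* **Backbone.** An order-$m$ Markov chain ($m \in \{0,1,2\}$) whose
  per-context distributions apply a complement-symmetric self-repetition
  bias (default 0.3) to a base composition; the composition is recalibrated
  by a one-dimensional root find so the *stationary* G+C equals the target.
  Realized G+C lands within ±0.01 of target at 100 kb.
* **Motif exclusion.** Avoided motifs (default GATC and CTAG, the
  Dam/Zim targets) are removed by iterative repair — resample the last
  base of an offending window — rather than whole-genome rejection, whose
  acceptance probability vanishes at 75 kb. Repairs respect structure:
  inside a CDS the enclosing codon is resampled from the allowed codon
  set; windows pinned against a stop codon swap the stop for another stop;
  windows touching the terminal repeat copy are repaired at the mirrored
  position in the leading copy and re-copied. The loop is bounded and
  raises a constructive-failure error for infeasible specs.
* **TDR.** Planted by copying the leading `tdr_length` bases over the
  terminal ones, then re-screened so that `find_tdr()` recovers exactly
  the planted length (accidental one-base extensions are broken in the
  margin after the leading copy).
* **CDS.** Codons are drawn i.i.d. from the base composition conditioned
  on excluding stop and cysteine codons (the conditional G+C is
  recalibrated to the target), so translations are realistic in
  composition while cysteines exist only where planted: CxxC genes get a
  TGC-x-x-TGC insert away from both termini of the protein. This makes
  census ground truth exact: `n` CxxC genes planted means exactly `n`
  found. Translations stored on the record are recomputed from the final
  repaired DNA with genetic code table 11.
* **Determinism.** One RNG stream per genome, seeded from the spec; the
  caller's RNG state is saved and restored, and the seed is recorded in
  the record description. Identical specs are byte-identical.

Defaults emulate a Serpecor1-like genome — 74,196 bp, 57% G+C, order-1
backbone, GATC/CTAG avoided, 320 bp TDR, 126 CDS with a 23/14 CxxC census —
so `generate_genome(synthetic_genome_spec(seed = s))` is a one-liner for a
study-condition genome.

What the simulator does *not* emulate is worth stating: real genomes have
operonic gene organization, promoter/intergenic-repeat structure, codon
usage shaped by tRNA pools, repeated gene families, and avoidance acquired
by selection (gradual depletion) rather than construction (hard absence).
Passing tests on synthetic genomes therefore demonstrate correctness of
the *measurements* — that planted signals are recovered exactly and nulls
calibrate — not that any biological conclusion transfers; analyses of real
data should treat the deposited sequences as the authority.

```{r example}
g <- generate_genome(synthetic_genome_spec(length_bp = 20000L,
                                           tdr_length = 300L, n_cds = 15L,
                                           cxxc_plant = c(5L, 3L), seed = 1))
genome_summary(list(g))
motif_odds(g, "GATC")
cxxc_census(g)
```

## Numerical choices and degenerate inputs

* Internal coordinates are 0-based half-open everywhere; all user-facing
  tables are 1-based inclusive (the GenBank convention). One convention
  for arithmetic, one for reading.
* `markov_expected()` refuses a zero-count core word by design (the
  expectation is undefined), naming the word; the census catches this per
  motif and reports `NA` odds rather than failing the panel.
* An all-N sequence has no defined G+C and errors; sequences mixing N are
  handled by window skipping.
* Ties in TDR length cannot arise at `max_mismatch = 0` (the maximal exact
  L is unique); with mismatches the largest qualifying L wins.
* `pairwise_identity()` on anchor-free pairs (unrelated sequences) returns
  identity 0 with coverage 0 rather than an error.
* FASTA/GenBank writers are byte-stable (no timestamps), so golden-file
  comparisons and regeneration checks are exact.

## Problem sizes in the shipped tests

The test-suite simulations are sized for a single CPU: calibration uses
twenty 100 kb genomes per Markov order, TDR recovery 100 planted instances
in the 250–400 bp study range on ~5 kb cores, oracle-equivalence checks run
at ≤ 200 bp (motif odds, against direct window arithmetic) and ≤ 500 bp
(identity, against full dynamic programming), and the acceptance script
regenerates one full-scale 74 kb study-condition genome plus smaller
panels. These sizes are the package's choice of a demonstrative, quickly
reproducible configuration; all operations run unchanged on full-size
genome sets.

## Reproducing published-scale analyses

The deposited HF1-group isolate genomes are not shipped (they are
GenBank's to distribute); `scripts/fetch_accessions.R` downloads them once
into a local cache, after which `replay_isolates()` recomputes the
avoidance matrix, TDR lengths, summaries, CxxC censuses and pairwise
identities from the deposited sequences, and the accession-replay test in
`tests/testthat/test-acceptance.R` checks them against the published
values. Without the cache that test fails by design — it is a statement
about data availability, not about the code.

## Known limitations

* The GenBank dialect read/written is minimal (LOCUS/FEATURES/ORIGIN, CDS
  with locus_tag/product/translation); compound `join()` locations are
  collapsed to their outer span, which is adequate for translation-based
  censuses but not for exon-accurate coordinate work.
* Identity estimation assumes substantial collinearity; heavily rearranged
  pairs will report low coverage rather than a rearrangement-aware
  identity.
* The mismatch-tolerant TDR search is quadratic and intended for draft
  checking, not for scanning large genome sets.
* Odds ratios come with no p-values; depletion significance testing is out
  of scope, as is discovery of avoided non-palindromic motifs.
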