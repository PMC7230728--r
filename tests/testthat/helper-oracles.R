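# Independent brute-force oracles and small fixture builders used across the
# suite. The oracles deliberately avoid the package's own code paths: direct
# window scans, direct frequency arithmetic, full dynamic-programming
# alignment.

rand_dna <- function(n, seed, probs = c(0.25, 0.25, 0.25, 0.25)) {
  withr::with_seed(seed,
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs),
          collapse = ""))
}

# direct window-scan count of exact occurrences (overlapping)
brute_count <- function(seq, word) {
  k <- nchar(word)
  n <- nchar(seq)
  if (n < k) return(0L)
  sum(substring(seq, 1:(n - k + 1L), k:n) == word)
}

# observed/expected odds by direct window scan + direct frequency arithmetic
brute_motif_odds <- function(seq, motif,
                             null_model = c("maximal_order", "zero_order")) {
  null_model <- match.arg(null_model)
  n <- nchar(seq)
  k <- nchar(motif)
  nw <- function(kk) n - kk + 1L
  obs <- brute_count(seq, motif)
  if (null_model == "zero_order") {
    bases <- strsplit(motif, "")[[1L]]
    exp_ <- nw(k) * prod(vapply(bases, function(b) brute_count(seq, b) / n, 0))
  } else {
    pre <- substr(motif, 1L, k - 1L)
    suf <- substr(motif, 2L, k)
    core <- substr(motif, 2L, k - 1L)
    exp_ <- nw(k) *
      (brute_count(seq, pre) / nw(k - 1L)) *
      (brute_count(seq, suf) / nw(k - 1L)) /
      (brute_count(seq, core) / nw(k - 2L))
  }
  list(observed = obs, expected = exp_, odds = obs / exp_)
}

# full-DP global alignment identity with the same column-counting convention
# and scoring as the package's gap-closure aligner
brute_identity_pct <- function(a_seq, b_seq) {
  aln <- Biostrings::pairwiseAlignment(
    a_seq, b_seq, type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -3, baseOnly = FALSE),
    gapOpening = 5, gapExtension = 2)
  100 * Biostrings::nmatch(aln) / Biostrings::nchar(aln)
}

# regex-based CxxC scan (lookahead for overlaps)
brute_cxxc <- function(aa) {
  hits <- gregexpr("(?=C..C)", aa, perl = TRUE)[[1L]]
  if (hits[1L] == -1L) integer() else as.integer(hits)
}

# sequence-only synthetic spec shorthand
seq_spec <- function(length_bp, seed, ...) {
  synthetic_genome_spec(length_bp = as.integer(length_bp), tdr_length = 0L,
                        n_cds = 0L, cxxc_plant = c(0L, 0L),
                        avoided_motifs = character(), seed = seed, ...)
}
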