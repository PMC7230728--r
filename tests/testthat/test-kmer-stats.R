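test_that("count_kmers enumerates overlapping windows and skips N windows", {
  t1 <- count_kmers(genome_record("a", "AAAA"), 4)
  expect_equal(t1$counts[["AAAA"]], 1L)
  expect_equal(t1$n_windows, 1L)

  t2 <- count_kmers(genome_record("b", "GATCGATC"), 4)
  expect_equal(t2$counts[["GATC"]], 2L)
  expect_equal(t2$counts[["ATCG"]], 1L)
  expect_equal(t2$counts[["TCGA"]], 1L)
  expect_equal(t2$counts[["CGAT"]], 1L)
  expect_equal(t2$n_windows, 5L)

  t3 <- count_kmers(genome_record("c", "GANTC"), 2)
  expect_equal(t3$counts[["GA"]], 1L)
  expect_equal(t3$counts[["TC"]], 1L)
  expect_equal(t3$n_windows, 2L)

  expect_error(count_kmers(genome_record("d", "ACG"), 4), "exceeds")
})

test_that("k-mer counts conserve windows and are consistent across k", {
  for (seed in 1:5) {
    x <- rand_dna(500, seed = 300 + seed)
    g <- genome_record("x", x)
    for (k in c(2L, 4L, 6L)) {
      tab <- count_kmers(g, k)
      expect_equal(tab$n_windows, 500L - k + 1L)
      expect_equal(sum(tab$counts), tab$n_windows)
    }
    # summing 4-mer counts over the final base recovers each 3-mer count,
    # corrected for the terminal 3-mer window that heads no 4-mer
    t4 <- count_kmers(g, 4L)
    t3 <- count_kmers(g, 3L)
    tail3 <- substr(x, 498, 500)
    for (w in c("ACG", "GGG", tail3)) {
      s4 <- sum(t4$counts[paste0(w, c("A", "C", "G", "T"))])
      expect_equal(s4, t3$counts[[w]] - as.integer(w == tail3))
    }
  }
})

test_that("circular topology adds wrap-around windows", {
  lin <- genome_record("l", "GATCGA")
  circ <- genome_record("c", "GATCGA", topology = "circular")
  expect_equal(count_kmers(lin, 4)$n_windows, 3L)
  expect_equal(count_kmers(circ, 4)$n_windows, 6L)
  # the wrap windows: CGAG? no - windows are CGAGA? check GAGA TCGA...
  expect_equal(count_kmers(circ, 4)$counts[["CGAG"]], 1L)
})

test_that("maximal-order expectation matches the closed-form hand computation", {
  # (GATC)x50: window counts GATC=50, GAT=ATC=50, AT=50 give
  # odds = 198^2 / (197 * 199)
  g <- genome_record("rep", strrep("GATC", 50))
  res <- motif_odds(g, "GATC", null_model = "maximal_order")
  expect_equal(res$odds, 198^2 / (197 * 199), tolerance = 1e-12)
  expect_equal(res$observed, 50L)
  expect_equal(res$classification, "normal")
})

test_that("zero-order expectation is near the realized count on i.i.d. sequence", {
  devs <- vapply(1:10, function(s) {
    g <- generate_genome(seq_spec(100000, seed = 400 + s, gc = 0.5,
                                  markov_order = 0L))
    r <- motif_odds(g, "GATC", null_model = "zero_order")
    r$observed / r$expected
  }, 0)
  expect_lt(abs(mean(devs) - 1), 0.05)
})

test_that("absent motifs have positive expectation, zero odds and 'absent' class", {
  g <- generate_genome(synthetic_genome_spec(
    length_bp = 20000L, avoided_motifs = "GATC", tdr_length = 0L,
    n_cds = 0L, cxxc_plant = c(0L, 0L), seed = 6))
  r <- motif_odds(g, "GATC")
  expect_equal(r$observed, 0L)
  expect_gt(r$expected, 0)
  expect_equal(r$odds, 0)
  expect_equal(r$classification, "absent")
})

test_that("markov_expected errors on a zero-count core word", {
  g <- genome_record("p", strrep("AC", 100))
  expect_error(motif_odds(g, "ATTA"), "core word TT")
})

test_that("motif_odds agrees with the brute-force oracle to 10 decimals", {
  for (seed in 1:20) {
    x <- rand_dna(sample(100:200, 1), seed = 500 + seed,
                  probs = c(0.2, 0.3, 0.3, 0.2))
    g <- genome_record("x", x)
    for (motif in c("GATC", "TGCA", "CTAG", "ACGT")) {
      oracle <- tryCatch(brute_motif_odds(x, motif), error = function(e) NULL)
      if (is.null(oracle) || !is.finite(oracle$expected)) next
      res <- motif_odds(g, motif)
      expect_equal(res$expected, oracle$expected, tolerance = 1e-10)
      expect_equal(res$observed, oracle$observed)
      oracle0 <- brute_motif_odds(x, motif, "zero_order")
      res0 <- motif_odds(g, motif, null_model = "zero_order")
      expect_equal(res0$expected, oracle0$expected, tolerance = 1e-10)
    }
  }
})

test_that("enumerate_palindromes returns exactly the self-reverse-complementary words", {
  expect_equal(enumerate_palindromes(2), c("AT", "CG", "GC", "TA"))
  p4 <- enumerate_palindromes(4)
  expect_length(p4, 16L)
  expect_true(all(c("GATC", "CTAG", "AGCT", "TGCA", "CATG") %in% p4))
  for (k in c(2L, 4L, 6L)) {
    pk <- enumerate_palindromes(k)
    expect_length(pk, 4L^(k / 2L))
    expect_false(is.unsorted(pk))
    expect_true(all(vapply(pk, function(w) reverse_complement(w) == w, TRUE)))
  }
  # exhaustive cross-check at k = 4 against all 256 words
  all4 <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), 4),
                                      stringsAsFactors = FALSE))
  truth <- sort(all4[vapply(all4, function(w) reverse_complement(w) == w,
                            TRUE)])
  expect_equal(p4, truth)
  expect_error(enumerate_palindromes(5), "even")
})

test_that("IUPAC motif counting handles ambiguity, N and both strands", {
  g <- genome_record("x", "GGACCGGTCC")
  expect_equal(count_ambiguous_motif(g, "GGWCC"), 2L)
  expect_equal(count_ambiguous_motif(genome_record("y", "AATTCGAAGG"),
                                     "TTCGAA"), 1L)
  expect_equal(count_ambiguous_motif(genome_record("z", "ACGTACGTAC"),
                                     "NNNNN"), 6L)
  # genome windows containing N never match
  expect_equal(count_ambiguous_motif(genome_record("n", "ACNTACGTAC"),
                                     "NNNNN"), 3L)
  expect_error(count_ambiguous_motif(g, "GGJCC"), "IUPAC")
  # non-self-complementary motif: reverse strand adds matches
  h <- genome_record("h", "AAAGGGTTTCCCTTT")
  expect_equal(count_ambiguous_motif(h, "GGG"), 1L)
  expect_equal(count_ambiguous_motif(h, "GGG", both_strands = TRUE), 2L)
  # self-complementary motifs count each duplex site once
  expect_equal(count_ambiguous_motif(genome_record("s", "TGATCA"), "GATC",
                                     both_strands = TRUE), 1L)
})

test_that("frameshift scan finds the TTT-CGN signal only on the coding strand", {
  # plus-strand CDS ending ...TTTCGC TGA
  core <- paste0("ATG", strrep("GAA", 20), "TTTCGC", "TGA")
  pad <- strrep("A", 10)
  seq <- paste0(pad, core, pad)
  g <- genome_record("fs", seq,
                     features = cds_features("FS_1", 10L, 10L + nchar(core),
                                             "+", "chaperone", ""))
  hits <- frameshift_motif_scan(g, window_bp = 15L)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$locus_tag, "FS_1")
  expect_equal(substr(core, hits$cds_position, hits$cds_position + 5L),
               "TTTCGC")

  # same motif placed on the template strand only: no hit
  core2 <- paste0("ATG", strrep("GAA", 20), reverse_complement("TTTCGC"),
                  "TGA")
  g2 <- genome_record("fs2", paste0(pad, core2, pad),
                      features = cds_features("FS_2", 10L,
                                              10L + nchar(core2), "+", "", ""))
  expect_equal(nrow(frameshift_motif_scan(g2, window_bp = 15L)), 0L)

  # minus-strand CDS: coding strand is the reverse complement
  g3 <- genome_record("fs3", paste0(pad, reverse_complement(core), pad),
                      features = cds_features("FS_3", 10L, 10L + nchar(core),
                                              "-", "", ""))
  hits3 <- frameshift_motif_scan(g3, window_bp = 15L)
  expect_equal(nrow(hits3), 1L)

  expect_warning(out <- frameshift_motif_scan(genome_record("e", "ACGTACGT")),
                 "no CDS")
  expect_equal(nrow(out), 0L)
})

test_that("palindrome census applies sub-motif exclusion and finds absences", {
  g1 <- generate_genome(synthetic_genome_spec(
    length_bp = 20000L, avoided_motifs = "GATC", tdr_length = 0L, n_cds = 0L,
    cxxc_plant = c(0L, 0L), seed = 21))
  cen <- palindrome_census(list(g1), k = 4)
  expect_true("GATC" %in% cen$absent_in_all)
  expect_length(cen$candidates, 16L)
  expect_length(cen$excluded, 0L)

  cen6 <- palindrome_census(list(g1), k = 6, exclude_submotifs = "CTAG")
  expect_true("ACTAGT" %in% cen6$excluded)   # contains CTAG
  expect_false("ACTAGT" %in% cen6$absent_in_all)
  expect_error(palindrome_census(list(g1), k = 4,
                                 exclude_submotifs = "GATC"), "shorter")
})
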