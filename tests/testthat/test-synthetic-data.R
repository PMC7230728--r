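test_that("spec validation rejects impossible parameter combinations", {
  expect_error(synthetic_genome_spec(length_bp = 500L, tdr_length = 300L),
               "exceed")
  expect_error(synthetic_genome_spec(gc = 1.2), "gc")
  expect_error(synthetic_genome_spec(markov_order = 3L), "markov_order")
  expect_error(synthetic_genome_spec(avoided_motifs = "GAXC"), "avoided")
  expect_error(synthetic_genome_spec(n_cds = 5L, cxxc_plant = c(7L, 2L)),
               "cxxc_plant")
})

test_that("generation is byte-deterministic in the seed and leaves the RNG alone", {
  spec <- synthetic_genome_spec(length_bp = 8000L, tdr_length = 260L,
                                n_cds = 6L, cxxc_plant = c(2L, 1L),
                                seed = 170)
  set.seed(999)
  g1 <- generate_genome(spec)
  draw1 <- runif(1)
  g2 <- generate_genome(spec)
  set.seed(999)
  g3 <- generate_genome(spec)
  draw2 <- runif(1)
  expect_identical(g1$sequence, g2$sequence)
  expect_identical(as.data.frame(g1$features), as.data.frame(g2$features))
  expect_identical(draw1, draw2)  # generator restores the caller's RNG state
  expect_identical(g1$sequence, g3$sequence)
  g4 <- generate_genome(synthetic_genome_spec(length_bp = 8000L,
                                              tdr_length = 260L, n_cds = 6L,
                                              cxxc_plant = c(2L, 1L),
                                              seed = 171))
  expect_false(identical(g1$sequence, g4$sequence))
})

test_that("avoided motifs are absent on both strands, including in CDS and TDR", {
  for (s in 1:5) {
    g <- generate_genome(synthetic_genome_spec(
      length_bp = 20000L, tdr_length = 300L, n_cds = 15L,
      cxxc_plant = c(4L, 2L), avoided_motifs = c("GATC", "CTAG", "AAGCTT"),
      seed = 180 + s))
    for (m in c("GATC", "CTAG", "AAGCTT")) {
      expect_equal(brute_count(g$sequence, m), 0L)
      expect_equal(brute_count(reverse_complement(g$sequence), m), 0L)
    }
  }
})

test_that("realized G+C tracks the target across orders", {
  for (m in 0:2) {
    g <- generate_genome(seq_spec(100000, seed = 190 + m, gc = 0.57,
                                  markov_order = m))
    expect_lt(abs(gc_content(g) - 0.57), 0.01)
  }
  g <- generate_genome(seq_spec(100000, seed = 194, gc = 0.40))
  expect_lt(abs(gc_content(g) - 0.40), 0.01)
})

test_that("planted structure is recovered by the analysis stack", {
  g <- generate_genome(synthetic_genome_spec(
    length_bp = 30000L, tdr_length = 306L, n_cds = 25L,
    cxxc_plant = c(6L, 4L), seed = 200))
  expect_equal(find_tdr(g)$length_bp, 306L)
  cen <- palindrome_census(list(g), k = 4)
  expect_true(all(c("GATC", "CTAG") %in% cen$absent_in_all))
  rep_ <- cxxc_census(g)
  expect_equal(rep_$n_cxxc_genes, 6L)
  expect_equal(rep_$n_micro_cxxc, 4L)
  expect_equal(nrow(g$features), 25L)
  # translations respect the declared spans
  expect_true(all(nchar(g$features$translation) ==
                    (g$features$end - g$features$start) / 3 - 1))
})

test_that("mutate_genome matches its binomial contract and is deterministic", {
  g <- generate_genome(seq_spec(5000, seed = 210))
  expect_identical(mutate_genome(g, 0, seed = 1)$sequence, g$sequence)
  m1 <- mutate_genome(g, 0.1, seed = 2)
  m2 <- mutate_genome(g, 0.1, seed = 2)
  expect_identical(m1$sequence, m2$sequence)
  expect_equal(nrow(m1$features), 0L)

  # expected substitutions = n * rate (rate chosen to give ~1 per genome)
  rate <- 1 / g$length_bp
  n_subs <- vapply(1:300, function(s) {
    mm <- mutate_genome(g, rate, seed = s)
    sum(strsplit(mm$sequence, "")[[1L]] != strsplit(g$sequence, "")[[1L]])
  }, 0)
  expect_lt(abs(mean(n_subs) - 1), 0.12)
  expect_error(mutate_genome(g, 0.7), "rate")
})

test_that("fixture_suite writes a parseable battery with a truthful manifest", {
  dir <- withr::local_tempdir()
  man <- fixture_suite(dir, seed = 5L)
  expect_true(all(file.exists(file.path(
    dir, c("avoided.fasta", "tdr.fasta", "cxxc.gbk", "pair_a.fasta",
           "pair_b.fasta")))))

  avoided <- read_fasta(file.path(dir, "avoided.fasta"))[[1L]]
  expect_equal(brute_count(avoided$sequence, "GATC"), 0L)
  expect_equal(avoided$length_bp, man$avoided.fasta$length_bp)

  tdr_g <- read_fasta(file.path(dir, "tdr.fasta"))[[1L]]
  expect_equal(find_tdr(tdr_g)$length_bp, man$tdr.fasta$tdr_length)

  cx <- read_genbank(file.path(dir, "cxxc.gbk"))[[1L]]
  rep_ <- cxxc_census(cx)
  expect_equal(rep_$n_cxxc_genes, man$cxxc.gbk$n_cxxc_genes)
  expect_equal(rep_$n_micro_cxxc, man$cxxc.gbk$n_micro_cxxc)

  # byte-identical regeneration
  dir2 <- withr::local_tempdir()
  fixture_suite(dir2, seed = 5L)
  for (f in c("avoided.fasta", "cxxc.gbk")) {
    expect_identical(readLines(file.path(dir, f)),
                     readLines(file.path(dir2, f)))
  }
})
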