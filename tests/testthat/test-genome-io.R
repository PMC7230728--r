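test_that("FASTA reading case-folds, handles empty files and multiple entries", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(">x some description\nacgt", f)
  recs <- read_fasta(f)
  expect_length(recs, 1L)
  expect_equal(recs[[1L]]$sequence, "ACGT")
  expect_equal(recs[[1L]]$length_bp, 4L)
  expect_equal(recs[[1L]]$id, "x")
  expect_equal(recs[[1L]]$description, "some description")
  expect_equal(recs[[1L]]$topology, "linear")

  empty <- withr::local_tempfile(fileext = ".fasta")
  file.create(empty)
  expect_length(read_fasta(empty), 0L)

  two <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", rand_dna(10, 1), ">b", rand_dna(20, 2)), two)
  recs <- read_fasta(two)
  expect_equal(vapply(recs, function(r) r$length_bp, 0L), c(10L, 20L))

  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines("ACGT no header", bad)
  expect_error(read_fasta(bad), "FASTA")
})

test_that("FASTA write/read round-trips sequences", {
  g <- generate_genome(seq_spec(3000, seed = 4))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(g, f)
  back <- read_fasta(f)[[1L]]
  expect_identical(back$sequence, g$sequence)
  expect_identical(back$id, g$id)
})

test_that("GenBank parsing uses 0-based half-open coordinates and verbatim translations", {
  f <- withr::local_tempfile(fileext = ".gbk")
  seq300 <- rand_dna(300, seed = 9)
  tr19 <- paste(rep("M", 19), collapse = "")
  writeLines(c(
    "LOCUS       test1 300 bp    DNA     linear   UNA",
    "DEFINITION  fixture record",
    "FEATURES             Location/Qualifiers",
    "     source          1..300",
    "     CDS             101..160",
    "                     /locus_tag=\"T_005\"",
    "                     /product=\"hypothetical protein\"",
    sprintf("                     /translation=\"%s\"", tr19),
    "ORIGIN",
    paste(" ", tolower(seq300)),
    "//"), f)
  rec <- read_genbank(f)[[1L]]
  expect_equal(rec$length_bp, 300L)
  expect_equal(rec$features$start, 100L)   # GenBank 101 -> internal 100
  expect_equal(rec$features$end, 160L)
  expect_equal(rec$features$strand, "+")
  expect_equal(nchar(rec$features$translation), 19L)  # stop codon excluded
  expect_equal(rec$features$locus_tag, "T_005")
})

test_that("GenBank reader rejects records without sequence and out-of-range features", {
  f <- withr::local_tempfile(fileext = ".gbk")
  writeLines(c("LOCUS       bad 10 bp", "FEATURES", "//"), f)
  expect_error(read_genbank(f), "ORIGIN")

  f2 <- withr::local_tempfile(fileext = ".gbk")
  writeLines(c(
    "LOCUS       bad2 10 bp",
    "FEATURES             Location/Qualifiers",
    "     CDS             1..60",
    "ORIGIN",
    "        1 acgtacgtac",
    "//"), f2)
  expect_error(read_genbank(f2), "past sequence end")
})

test_that("GenBank write/read round-trips sequence and feature tuples", {
  # includes minus-strand features and multi-line translations
  for (seed in c(3L, 8L)) {
    g <- generate_genome(synthetic_genome_spec(
      length_bp = 9000L, tdr_length = 260L, n_cds = 5L,
      cxxc_plant = c(2L, 1L), seed = seed))
    f <- withr::local_tempfile(fileext = ".gbk")
    write_genbank(g, f)
    back <- read_genbank(f)[[1L]]
    expect_identical(back$sequence, g$sequence)
    expect_identical(as.data.frame(back$features), as.data.frame(g$features))
    expect_identical(back$topology, g$topology)
  }
})

test_that("GenBank writer handles feature-free records and large genomes", {
  g <- genome_record("bare", rand_dna(1000, 5))
  f <- withr::local_tempfile(fileext = ".gbk")
  write_genbank(g, f)
  expect_false(any(grepl("^     CDS", readLines(f))))
  back <- read_genbank(f)[[1L]]
  expect_identical(back$sequence, g$sequence)
  expect_equal(nrow(back$features), 0L)
})

test_that("reverse_complement is a length-preserving involution with N fixed", {
  expect_equal(reverse_complement("GATC"), "GATC")
  expect_equal(reverse_complement("AAAC"), "GTTT")
  expect_equal(reverse_complement("ANT"), "ANT")
  expect_error(reverse_complement("AXGT"), "outside")
  for (seed in 1:25) {
    x <- rand_dna(sample(1:80, 1), seed = 100 + seed)
    expect_identical(reverse_complement(reverse_complement(x)), x)
    expect_equal(nchar(reverse_complement(x)), nchar(x))
  }
})

test_that("gc_content matches definition and is reverse-complement invariant", {
  expect_equal(gc_content("GCGC"), 1.0)
  expect_equal(gc_content("ATAT"), 0.0)
  expect_equal(gc_content("GCAT"), 0.5)
  expect_equal(gc_content("GCNN"), 1.0)     # N excluded from the denominator
  expect_error(gc_content("NNN"), "all N")
  for (seed in 1:10) {
    x <- rand_dna(200, seed = 200 + seed, probs = c(0.2, 0.3, 0.3, 0.2))
    expect_equal(gc_content(x), gc_content(reverse_complement(x)))
  }
})

test_that("provirus linearization rotates the excised circle correctly", {
  host <- genome_record("host", "TTTAAACCCGGGTTT")
  # excise [3, 12) = AAACCCGGG
  expect_equal(linearize_provirus(host, 3, 12, 0)$sequence, "AAACCCGGG")
  expect_equal(linearize_provirus(host, 3, 12, 3)$sequence, "CCCGGGAAA")
  expect_error(linearize_provirus(host, 3, 12, 9), "out of range")
  expect_error(linearize_provirus(host, 12, 3, 0), "att coordinates")

  # rotation by L then by (n - L) restores the segment; bases conserved
  seg_len <- 9L
  for (L in 0:8) {
    once <- linearize_provirus(host, 3, 12, L)
    expect_equal(sort(strsplit(once$sequence, "")[[1L]]),
                 sort(strsplit("AAACCCGGG", "")[[1L]]))
    back <- linearize_provirus(
      genome_record("c", once$sequence), 0, seg_len,
      (seg_len - L) %% seg_len)
    expect_equal(back$sequence, "AAACCCGGG")
  }
})
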