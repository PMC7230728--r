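#' Multi-genome palindrome avoidance census
#'
#' Runs the avoidance statistic over every reverse-complement palindrome of
#' length `k` across a set of genomes, applies the sub-motif exclusion rule
#' (a longer palindrome is dropped when it contains an already-avoided
#' shorter motif, whose absence trivially forces absence of the longer one),
#' and reports the set of palindromes absent in every genome.
#'
#' @param genomes List of `GenomeRecord`s (>= 1).
#' @param k Even palindrome length.
#' @param exclude_submotifs Character vector of shorter motifs; any candidate
#'   containing one of them as a substring is excluded.
#' @param null_model Passed to [motif_odds()].
#' @param under_threshold Passed to [motif_odds()].
#' @return A `PalindromeCensus`: list with `k`, `genomes` (ids, input order),
#'   `table` (long data frame: genome, motif, observed, expected, odds,
#'   classification), `candidates`, `excluded`, `absent_in_all`.
#' @export
palindrome_census <- function(genomes, k, exclude_submotifs = character(),
                              null_model = "maximal_order",
                              under_threshold = 0.78) {
  if (inherits(genomes, "GenomeRecord")) genomes <- list(genomes)
  stopifnot(length(genomes) >= 1L)
  exclude_submotifs <- toupper(exclude_submotifs)
  if (any(nchar(exclude_submotifs) >= k)) {
    stop("exclude_submotifs must be shorter than k", call. = FALSE)
  }
  candidates <- enumerate_palindromes(k)
  excluded <- candidates[vapply(candidates, function(w) {
    any(vapply(exclude_submotifs, function(s) grepl(s, w, fixed = TRUE),
               FALSE))
  }, FALSE)]
  kept <- setdiff(candidates, excluded)

  rows <- lapply(genomes, function(g) {
    ks <- if (null_model == "maximal_order") c(k, k - 1L, k - 2L) else c(k, 1L)
    tables <- lapply(unique(ks), function(kk) count_kmers(g, kk))
    do.call(rbind, lapply(candidates, function(w) {
      observed <- tables[[1L]]$counts[[w]]
      expected <- tryCatch(markov_expected(w, tables, null_model),
                           error = function(e) NA_real_)
      odds <- if (!is.na(expected) && expected > 0) observed / expected
              else NA_real_
      classification <- if (observed == 0L) "absent"
        else if (!is.na(odds) && odds < under_threshold) "under_represented"
        else "normal"
      data.frame(genome = g$id, motif = w, observed = observed,
                 expected = expected, odds = odds,
                 classification = classification, stringsAsFactors = FALSE)
    }))
  })
  tab <- do.call(rbind, rows)
  zero_everywhere <- vapply(kept, function(w) {
    all(tab$observed[tab$motif == w] == 0L)
  }, FALSE)
  structure(
    list(k = k, genomes = vapply(genomes, function(g) g$id, ""),
         table = tab, candidates = candidates, excluded = excluded,
         absent_in_all = kept[zero_everywhere]),
    class = "PalindromeCensus"
  )
}

#' @export
print.PalindromeCensus <- function(x, ...) {
  cat(sprintf(
    "PalindromeCensus k=%d over %d genome(s): %d candidates, %d excluded,\n",
    x$k, length(x$genomes), length(x$candidates), length(x$excluded)))
  cat(sprintf("  %d palindromes absent in all genomes\n",
              length(x$absent_in_all)))
  invisible(x)
}

#' Count matches of an IUPAC-ambiguous motif
#'
#' Overlapping matches of a motif written with IUPAC ambiguity codes
#' (e.g. `GGWCC`, `W = A/T`). Matching is by per-position base-set
#' membership; windows containing `N` in the genome never match. When
#' `both_strands` is set and the motif is not its own reverse complement
#' under IUPAC expansion, reverse-strand matches are added; self-complementary
#' motifs are counted on the forward strand only (each duplex site once).
#'
#' @inheritParams count_kmers
#' @param iupac_motif Motif over the IUPAC alphabet.
#' @param both_strands Count reverse-strand matches of non-self-complementary
#'   motifs as well.
#' @return Integer match count.
#' @export
#' @examples
#' count_ambiguous_motif(genome_record("x", "GGACCGGTCC"), "GGWCC")
count_ambiguous_motif <- function(record, iupac_motif, both_strands = FALSE) {
  if (is.character(record)) record <- genome_record("seq", record)
  iupac_motif <- toupper(iupac_motif)
  if (grepl("[^ACGTRYSWKMBDHVN]", iupac_motif)) {
    stop("invalid IUPAC code in motif: ", iupac_motif, call. = FALSE)
  }
  n_fwd <- .count_iupac_fwd(record$sequence, iupac_motif)
  if (!both_strands) return(n_fwd)
  rc <- .iupac_revcomp(iupac_motif)
  if (rc == iupac_motif) return(n_fwd)  # self-complementary: one duplex site
  n_fwd + .count_iupac_fwd(record$sequence, rc)
}

.count_iupac_fwd <- function(seq, motif) {
  subj <- Biostrings::DNAString(seq)
  hits <- Biostrings::matchPattern(Biostrings::DNAString(motif), subj,
                                   fixed = c(pattern = FALSE, subject = TRUE))
  if (length(hits) == 0L) return(0L)
  # N-containing genome windows are skipped, never treated as matches
  frag <- as.character(hits)
  sum(!grepl("N", frag, fixed = TRUE))
}

.iupac_revcomp <- function(motif) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N")
  paste(rev(comp[strsplit(motif, "")[[1L]]]), collapse = "")
}

#' Scan CDS ends for a +1 frameshift candidate motif
#'
#' In tailed viruses the chaperone pair upstream of the tape-measure-protein
#' gene is often fused by programmed translational frameshifting. This scan
#' looks, for each CDS, for a motif (default `TTTCGN`, the TTT-CGN signal
#' implicated in +1 frameshifts) within the final `window_bp` coding-strand
#' nucleotides immediately preceding the stop codon.
#'
#' @inheritParams count_kmers
#' @param motif IUPAC motif scanned on the coding strand.
#' @param window_bp Window length upstream of the stop codon (default 15).
#' @return Data frame with one row per hit: `locus_tag`, `cds_position`
#'   (1-based position of the motif start within the CDS), `genomic_position`
#'   (1-based on the forward genome strand). Empty (with a warning) when the
#'   record has no CDS.
#' @export
frameshift_motif_scan <- function(record, motif = "TTTCGN", window_bp = 15L) {
  stopifnot(inherits(record, "GenomeRecord"))
  empty <- data.frame(locus_tag = character(), cds_position = integer(),
                      genomic_position = integer(), stringsAsFactors = FALSE)
  ft <- record$features
  if (!nrow(ft)) {
    warning("record ", record$id, " has no CDS features")
    return(empty)
  }
  motif <- toupper(motif)
  mk <- nchar(motif)
  out <- list()
  for (i in seq_len(nrow(ft))) {
    cds <- substr(record$sequence, ft$start[i] + 1L, ft$end[i])
    if (ft$strand[i] == "-") cds <- reverse_complement(cds)
    len <- nchar(cds)
    if (len <= 3L) next
    region_end <- len - 3L                      # exclude the stop codon
    region_start <- max(1L, region_end - window_bp + 1L)
    region <- substr(cds, region_start, region_end)
    if (nchar(region) < mk) next
    hits <- Biostrings::matchPattern(
      Biostrings::DNAString(motif), Biostrings::DNAString(region),
      fixed = c(pattern = FALSE, subject = TRUE))
    for (h in seq_along(hits)) {
      if (grepl("N", as.character(hits[h]), fixed = TRUE)) next
      cds_pos <- region_start + Biostrings::start(hits)[h] - 1L
      genomic_pos <- if (ft$strand[i] == "+") {
        ft$start[i] + cds_pos
      } else {
        ft$end[i] - cds_pos - mk + 2L
      }
      out[[length(out) + 1L]] <- data.frame(
        locus_tag = ft$locus_tag[i], cds_position = cds_pos,
        genomic_position = genomic_pos, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}
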