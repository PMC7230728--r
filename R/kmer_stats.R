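#' Count overlapping k-mers of a genome
#'
#' Counts all overlapping forward-strand k-mer windows. Windows containing
#' `N` are skipped, never imputed. For circular records the k-1 wrap-around
#' windows are included, so a provirus circle and a linear virion genome are
#' both well defined; for a linear N-free sequence the number of valid
#' windows is `n - k + 1`.
#'
#' Forward-strand counting is the convention throughout: every motif in the
#' avoidance analyses is a reverse-complement palindrome, for which forward
#' counts are strand-symmetric.
#'
#' @param record A `GenomeRecord` (or DNA string, treated as linear).
#' @param k Word length, `1 <= k <=` sequence length.
#' @return A `KmerCountTable`: list with `k`, `counts` (named integer vector
#'   over all 4^k ACGT words), `n_windows`, `source_id`, `topology`.
#' @export
#' @examples
#' count_kmers(genome_record("x", "GATCGATC"), 4)$counts[c("GATC", "ATCG")]
count_kmers <- function(record, k) {
  if (is.character(record)) record <- genome_record("seq", record)
  stopifnot(inherits(record, "GenomeRecord"))
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (k > record$length_bp) {
    stop("k (", k, ") exceeds sequence length (", record$length_bp,
         "): no windows to count", call. = FALSE)
  }
  seq <- record$sequence
  if (record$topology == "circular" && k > 1L) {
    seq <- paste0(seq, substr(record$sequence, 1L, k - 1L))
  }
  counts <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(seq),
                                                 width = k)
  structure(
    list(k = k, counts = counts, n_windows = sum(counts),
         source_id = record$id, topology = record$topology),
    class = "KmerCountTable"
  )
}

#' @export
print.KmerCountTable <- function(x, ...) {
  cat(sprintf("KmerCountTable k=%d, %d windows, source %s (%s)\n", x$k,
              x$n_windows, x$source_id, x$topology))
  invisible(x)
}

#' Markov-model expected count of a motif
#'
#' Expected number of occurrences of a word under a Markov null built from
#' the genome's own sub-word frequencies.
#'
#' Under the maximal-order model (the standard null for oligonucleotide
#' relative-abundance studies) the expectation of word `w` of length k is
#' \deqn{E(w) = N_k \cdot \frac{f(w_{1..k-1}) \, f(w_{2..k})}{f(w_{2..k-1})}}
#' where `N_k` is the number of valid k-windows and `f` are the observed
#' frequencies of the length k-1 prefix, length k-1 suffix and length k-2
#' core in their respective window counts. Under `zero_order` the expectation
#' is `N_k` times the product of the single-base frequencies.
#'
#' @param motif Word over `{A,C,G,T}`.
#' @param tables List of `KmerCountTable`s from the same record, containing
#'   (for `maximal_order`) k, k-1 and k-2, or (for `zero_order`) k and 1.
#' @param null_model `"maximal_order"` or `"zero_order"`.
#' @return Positive expected count.
#' @export
markov_expected <- function(motif, tables,
                            null_model = c("maximal_order", "zero_order")) {
  null_model <- match.arg(null_model)
  motif <- toupper(motif)
  if (grepl("[^ACGT]", motif)) {
    stop("motif must be over {A,C,G,T}: ", motif, call. = FALSE)
  }
  k <- nchar(motif)
  tabs <- stats::setNames(tables, vapply(tables, function(t) t$k, 0L))
  src <- unique(vapply(tables, function(t) t$source_id, ""))
  if (length(src) != 1L) {
    stop("all KmerCountTables must come from the same record", call. = FALSE)
  }
  tk <- tabs[[as.character(k)]]
  if (is.null(tk)) stop("no KmerCountTable at k=", k, call. = FALSE)
  f_of <- function(word) {
    t <- tabs[[as.character(nchar(word))]]
    if (is.null(t)) stop("no KmerCountTable at k=", nchar(word), call. = FALSE)
    cnt <- t$counts[[word]]
    if (is.null(cnt)) cnt <- 0
    list(count = cnt, freq = cnt / t$n_windows)
  }
  if (null_model == "zero_order") {
    bases <- strsplit(motif, "")[[1L]]
    return(tk$n_windows * prod(vapply(bases, function(b) f_of(b)$freq, 0)))
  }
  if (k < 3L) {
    stop("maximal_order null requires k >= 3 (needs a k-2 core)",
         call. = FALSE)
  }
  pre <- substr(motif, 1L, k - 1L)
  suf <- substr(motif, 2L, k)
  core <- substr(motif, 2L, k - 1L)
  fc <- f_of(core)
  if (fc$count == 0) {
    stop("expectation undefined: core word ", core, " has zero count",
         call. = FALSE)
  }
  tk$n_windows * f_of(pre)$freq * f_of(suf)$freq / fc$freq
}

#' Observed/expected odds for a motif in a genome
#'
#' The per-genome avoidance statistic: observed count of the motif divided by
#' its Markov-model expectation. Values well below 1 indicate avoidance, the
#' hallmark of restriction-site counter-selection in virus genomes; an
#' observed count of 0 is classified `absent`.
#'
#' @inheritParams count_kmers
#' @param motif Word over `{A,C,G,T}`.
#' @param null_model `"maximal_order"` (default) or `"zero_order"`.
#' @param under_threshold Odds below which a non-absent motif is classified
#'   `under_represented` (default 0.78, the conventional cut for tetramer
#'   relative abundance).
#' @return A `MotifOddsResult`: list with `motif`, `observed`, `expected`,
#'   `odds` (raw; rendered to 2 decimals by report layers), `null_model`,
#'   `classification` in `{absent, under_represented, normal}`.
#' @export
motif_odds <- function(record, motif,
                       null_model = c("maximal_order", "zero_order"),
                       under_threshold = 0.78) {
  if (is.character(record)) record <- genome_record("seq", record)
  null_model <- match.arg(null_model)
  motif <- toupper(motif)
  k <- nchar(motif)
  ks <- if (null_model == "maximal_order") c(k, k - 1L, k - 2L) else c(k, 1L)
  tables <- lapply(unique(ks), function(kk) count_kmers(record, kk))
  observed <- tables[[1L]]$counts[[motif]]
  if (is.null(observed)) observed <- 0L
  expected <- markov_expected(motif, tables, null_model)
  odds <- if (expected > 0) observed / expected else NA_real_
  classification <- if (observed == 0L) {
    "absent"
  } else if (!is.na(odds) && odds < under_threshold) {
    "under_represented"
  } else "normal"
  structure(
    list(motif = motif, observed = as.integer(observed), expected = expected,
         odds = odds, null_model = null_model,
         classification = classification, source_id = record$id),
    class = "MotifOddsResult"
  )
}

#' @export
print.MotifOddsResult <- function(x, ...) {
  cat(sprintf("%s in %s: observed %d, expected %.2f, odds %.2f (%s, %s)\n",
              x$motif, x$source_id, x$observed, x$expected,
              if (is.na(x$odds)) NA else x$odds, x$classification,
              x$null_model))
  invisible(x)
}

#' Enumerate reverse-complement palindromes
#'
#' All DNA words of even length k equal to their own reverse complement — the
#' typical recognition-site shape of type II restriction-modification
#' systems. There are exactly `4^(k/2)` of them (the first half determines
#' the second); returned in lexicographic order.
#'
#' @param k Even word length >= 2.
#' @return Character vector of palindromes.
#' @export
#' @examples
#' enumerate_palindromes(2)  # AT, CG, GC, TA
enumerate_palindromes <- function(k) {
  k <- as.integer(k)
  if (k < 2L || k %% 2L != 0L) {
    stop("reverse-complement palindromes require even k >= 2", call. = FALSE)
  }
  half <- k %/% 2L
  halves <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), half),
                                        stringsAsFactors = FALSE))
  sort(vapply(halves, function(u) paste0(u, reverse_complement(u)), "",
              USE.NAMES = FALSE))
}
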