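#' Find the terminal direct repeat of a linear genome
#'
#' Linear dsDNA virion genomes of the HF1 group carry the same sequence
#' copied at both termini (a terminal direct repeat, TDR). This returns the
#' largest `L <= n/2` for which the Hamming distance between the first and
#' last `L` bases is at most `max_mismatch`; the cap at `n/2` keeps the two
#' copies from overlapping. An `L` below `min_len` is reported as length 0
#' (no TDR). With the default `max_mismatch = 0` the repeat copies must be
#' identical, the situation in deposited genomes; a mismatch tolerance is
#' available for draft assemblies. When several `L` satisfy a nonzero
#' mismatch bound, the largest is returned.
#'
#' @param record Linear `GenomeRecord` (or DNA string).
#' @param min_len Minimum repeat length considered real (default 20).
#' @param max_mismatch Maximum Hamming mismatches tolerated (default 0).
#' @return A `TDRResult`: list with `length_bp`, `repeat_sequence`,
#'   `left_interval` and `right_interval` (1-based inclusive start/end pairs;
#'   `c(0, 0)` when no TDR), `mismatches`.
#' @export
find_tdr <- function(record, min_len = 20L, max_mismatch = 0L) {
  if (is.character(record)) record <- genome_record("seq", record)
  stopifnot(inherits(record, "GenomeRecord"))
  if (record$topology != "linear") {
    stop("find_tdr requires a linear genome (a circle has no termini)",
         call. = FALSE)
  }
  if (min_len < 1L) stop("min_len must be >= 1", call. = FALSE)
  n <- record$length_bp
  r <- charToRaw(record$sequence)
  lmax <- n %/% 2L
  best <- 0L
  best_mm <- 0L
  if (max_mismatch == 0L) {
    probe <- 16L  # cheap prefix filter before the full comparison
    for (L in seq.int(lmax, min_len)) {
      off <- n - L
      p <- min(probe, L)
      if (!identical(r[seq_len(p)], r[off + seq_len(p)])) next
      if (identical(r[seq_len(L)], r[off + seq_len(L)])) {
        best <- L
        break
      }
    }
  } else {
    for (L in seq.int(lmax, min_len)) {
      off <- n - L
      mm <- sum(r[seq_len(L)] != r[off + seq_len(L)])
      if (mm <= max_mismatch) {
        best <- L
        best_mm <- mm
        break
      }
    }
  }
  if (best < min_len) best <- 0L
  structure(
    list(length_bp = best,
         repeat_sequence = if (best) substr(record$sequence, 1L, best) else "",
         left_interval = if (best) c(1L, best) else c(0L, 0L),
         right_interval = if (best) c(n - best + 1L, n) else c(0L, 0L),
         mismatches = best_mm, source_id = record$id),
    class = "TDRResult"
  )
}

#' @export
print.TDRResult <- function(x, ...) {
  if (x$length_bp == 0L) {
    cat(sprintf("TDRResult %s: no terminal direct repeat\n", x$source_id))
  } else {
    cat(sprintf(
      "TDRResult %s: %d bp TDR (left %d..%d, right %d..%d, %d mismatches)\n",
      x$source_id, x$length_bp, x$left_interval[1L], x$left_interval[2L],
      x$right_interval[1L], x$right_interval[2L], x$mismatches))
  }
  invisible(x)
}

#' Batch terminal-direct-repeat report
#'
#' One row per genome, in input order: TDR length and the G+C fraction of the
#' repeat itself.
#'
#' @param genomes List of linear `GenomeRecord`s.
#' @inheritParams find_tdr
#' @return Data frame with columns `genome`, `tdr_length`, `tdr_sequence`,
#'   `gc_of_tdr` (NA when no TDR).
#' @export
tdr_report <- function(genomes, min_len = 20L, max_mismatch = 0L) {
  if (inherits(genomes, "GenomeRecord")) genomes <- list(genomes)
  do.call(rbind, lapply(genomes, function(g) {
    res <- find_tdr(g, min_len = min_len, max_mismatch = max_mismatch)
    data.frame(
      genome = g$id, tdr_length = res$length_bp,
      tdr_sequence = res$repeat_sequence,
      gc_of_tdr = if (res$length_bp) gc_content(res$repeat_sequence)
                  else NA_real_,
      stringsAsFactors = FALSE)
  }))
}
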