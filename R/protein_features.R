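#' Scan a protein for CxxC motifs
#'
#' Positions of the zinc-finger signature C-x-x-C: residue `i` and residue
#' `i+3` are both cysteine, with two arbitrary residues between. Overlapping
#' matches are all reported. Exactly this spacing is scanned by default;
#' alternative spacings can be requested.
#'
#' @param protein_sequence Amino-acid string over the 20 standard residues
#'   plus `X` (a trailing `*` is tolerated and stripped).
#' @param spacing Number of residues between the two cysteines (default 2).
#' @return Integer vector of 1-based positions of the first cysteine of each
#'   match (empty for an empty sequence).
#' @export
#' @examples
#' scan_cxxc("ACDDCA")   # 2
#' scan_cxxc("CAACAAC")  # 1, 4
scan_cxxc <- function(protein_sequence, spacing = 2L) {
  protein_sequence <- toupper(sub("\\*$", "", protein_sequence))
  if (!nzchar(protein_sequence)) return(integer())
  if (grepl("[^ACDEFGHIKLMNPQRSTVWYX]", protein_sequence)) {
    stop("invalid amino-acid characters in protein sequence", call. = FALSE)
  }
  ch <- strsplit(protein_sequence, "")[[1L]]
  n <- length(ch)
  step <- spacing + 1L
  if (n < step + 1L) return(integer())
  i <- seq_len(n - step)
  i[ch[i] == "C" & ch[i + step] == "C"]
}

#' Census of CxxC-motif proteins in an annotated genome
#'
#' Counts, per genome, the CDS whose protein carries at least one CxxC motif
#' — the zinc-finger signature that is strikingly frequent among the small
#' proteins of HF1-group haloviruses — and how many of those are
#' micro-proteins (length strictly below `micro_threshold` amino acids).
#' Proteins come from the `/translation` qualifier when present, otherwise
#' from translating the CDS coordinates with genetic code table 11 (stop
#' trimmed); CDS with neither a translation nor a clean coding span are
#' skipped with a warning and tallied.
#'
#' @param record `GenomeRecord` with CDS features.
#' @param micro_threshold Micro-protein boundary in amino acids (default 100;
#'   strictly less-than).
#' @return A `CxxCReport`: list with `genome_id`, `per_protein` (data frame:
#'   locus_tag, start, end, length_aa, motif_count, positions), `n_cxxc_genes`,
#'   `n_micro_cxxc`, `micro_threshold`, `n_skipped`.
#' @export
cxxc_census <- function(record, micro_threshold = 100L) {
  stopifnot(inherits(record, "GenomeRecord"))
  ft <- record$features
  rows <- list()
  n_skipped <- 0L
  for (i in seq_len(nrow(ft))) {
    aa <- ft$translation[i]
    if (!nzchar(aa)) {
      aa <- tryCatch(
        translate_cds(record, ft$start[i], ft$end[i], ft$strand[i]),
        error = function(e) "")
      if (!nzchar(aa)) {
        warning("skipping CDS ", ft$locus_tag[i],
                ": no translation and no clean coding span")
        n_skipped <- n_skipped + 1L
        next
      }
    }
    pos <- scan_cxxc(aa)
    rows[[length(rows) + 1L]] <- data.frame(
      locus_tag = ft$locus_tag[i], start = ft$start[i], end = ft$end[i],
      length_aa = nchar(sub("\\*$", "", aa)), motif_count = length(pos),
      positions = paste(pos, collapse = ","), stringsAsFactors = FALSE)
  }
  per_protein <- if (length(rows)) do.call(rbind, rows) else
    data.frame(locus_tag = character(), start = integer(), end = integer(),
               length_aa = integer(), motif_count = integer(),
               positions = character(), stringsAsFactors = FALSE)
  hit <- per_protein$motif_count >= 1L
  structure(
    list(genome_id = record$id, per_protein = per_protein,
         n_cxxc_genes = sum(hit),
         n_micro_cxxc = sum(hit & per_protein$length_aa < micro_threshold),
         micro_threshold = as.integer(micro_threshold),
         n_skipped = n_skipped),
    class = "CxxCReport"
  )
}

#' @export
print.CxxCReport <- function(x, ...) {
  cat(sprintf(
    "CxxCReport %s: %d CxxC-motif genes (%d micro-proteins < %d aa) of %d CDS\n",
    x$genome_id, x$n_cxxc_genes, x$n_micro_cxxc, x$micro_threshold,
    nrow(x$per_protein)))
  if (x$n_skipped) cat(sprintf("  %d CDS skipped\n", x$n_skipped))
  invisible(x)
}

#' CxxC gene density within a genomic region
#'
#' Number of CxxC-positive CDS whose interval overlaps a query interval —
#' used to show the uneven genomic distribution of zinc-finger micro-protein
#' genes (e.g. their complete absence from the virion assembly module).
#'
#' @param report A `CxxCReport` from [cxxc_census()].
#' @param record The `GenomeRecord` the report was computed on.
#' @param interval Length-2 vector, 0-based half-open `[from, to)`.
#' @return Integer count.
#' @export
region_density <- function(report, record, interval) {
  stopifnot(inherits(report, "CxxCReport"), inherits(record, "GenomeRecord"))
  if (length(interval) != 2L || interval[1L] >= interval[2L]) {
    stop("interval must be an increasing pair [from, to)", call. = FALSE)
  }
  if (interval[1L] < 0 || interval[2L] > record$length_bp) {
    stop("interval outside the genome [0, ", record$length_bp, ")",
         call. = FALSE)
  }
  pp <- report$per_protein
  hit <- pp$motif_count >= 1L
  sum(hit & pp$start < interval[2L] & pp$end > interval[1L])
}

#' Translate a CDS span
#'
#' Translates genomic coordinates with genetic code table 11 (bacterial/
#' archaeal/plant plastid), trimming the terminal stop.
#'
#' @param record `GenomeRecord`.
#' @param start,end 0-based half-open span; `end - start` must be a multiple
#'   of 3.
#' @param strand `"+"` or `"-"`.
#' @return Amino-acid string.
#' @export
translate_cds <- function(record, start, end, strand = "+") {
  if ((end - start) %% 3L != 0L) {
    stop("CDS span is not a multiple of 3", call. = FALSE)
  }
  dna <- substr(record$sequence, start + 1L, end)
  if (strand == "-") dna <- reverse_complement(dna)
  if (grepl("N", dna, fixed = TRUE)) {
    stop("CDS span contains N; cannot translate", call. = FALSE)
  }
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(dna),
    genetic.code = Biostrings::getGeneticCode("11")))
  sub("\\*$", "", aa)
}
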