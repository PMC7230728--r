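#' Read genomes from a FASTA file
#'
#' Parses a (multi-)FASTA file into a list of [genome_record()] objects.
#' Sequences are uppercased; topology defaults to linear, which is the virion
#' state of the HF1-group genomes this package targets.
#'
#' @param path FASTA file.
#' @param topology Topology assigned to every record.
#' @return List of `GenomeRecord` (empty list for an empty file).
#' @export
read_fasta <- function(path, topology = "linear") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L) return(list())
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("^>", lines))) {
    if (all(!nzchar(trimws(lines)))) return(list())
    stop("malformed FASTA (no '>' header) in ", path, call. = FALSE)
  }
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) stop("FASTA parse error in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  lapply(seq_along(set), function(i) {
    header <- names(set)[i]
    id <- sub("\\s.*$", "", header)
    desc <- sub("^\\S+\\s*", "", header)
    genome_record(id, as.character(set[[i]]), description = desc,
                  topology = topology)
  })
}

#' Write genomes to a FASTA file
#'
#' @param records A `GenomeRecord` or list of them.
#' @param path Output file.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (inherits(records, "GenomeRecord")) records <- list(records)
  con <- file(path, "w")
  on.exit(close(con))
  for (rec in records) {
    header <- if (nzchar(rec$description)) {
      paste(rec$id, rec$description)
    } else rec$id
    writeLines(paste0(">", header), con)
    starts <- seq(1L, rec$length_bp, by = width)
    writeLines(substring(rec$sequence, starts,
                         pmin(starts + width - 1L, rec$length_bp)), con)
  }
  invisible(path)
}

#' Reverse complement of a DNA string
#'
#' Standard Watson-Crick complement, reversed; `N` maps to `N`. This is the
#' primitive behind the reverse-complement palindrome definition used
#' throughout the motif-avoidance analyses.
#'
#' @param sequence DNA string over `{A,C,G,T,N}`.
#' @return The reverse complement, same length.
#' @export
#' @examples
#' reverse_complement("GATC")  # "GATC": a self-complementary palindrome
reverse_complement <- function(sequence) {
  if (grepl("[^ACGTNacgtn]", sequence)) {
    stop("reverse_complement: characters outside {A,C,G,T,N}", call. = FALSE)
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
}

#' G+C content of a genome
#'
#' Fraction (G + C) over all non-N bases, in `[0, 1]`. Reporting layers render
#' this as a percentage with one decimal, the convention of genome summary
#' tables.
#'
#' @param x A `GenomeRecord` or DNA string.
#' @return Numeric fraction in `[0, 1]`.
#' @export
gc_content <- function(x) {
  seq <- if (inherits(x, "GenomeRecord")) x$sequence else .clean_dna(x)
  non_n <- nchar(gsub("N", "", seq, fixed = TRUE))
  if (non_n == 0L) stop("gc_content undefined: sequence is all N", call. = FALSE)
  gc <- nchar(seq) - nchar(gsub("[GC]", "", seq))
  gc / non_n
}

#' Excise and linearize an integrated provirus
#'
#' Emulates the in-silico handling of chromosomally integrated HF1-group
#' proviruses: the segment between the attachment sites is excised as a
#' circle and re-opened at the probable genome terminus (the position where
#' the terminal direct repeat of the virion form begins), yielding the linear
#' virion-like genome.
#'
#' All coordinates are 0-based; the excised segment is
#' `[att_left, att_right)` and `terminus_offset` indexes into that segment.
#'
#' @param host_segment `GenomeRecord` holding the host region (or contig).
#' @param att_left,att_right Attachment-site coordinates, `att_left < att_right`.
#' @param terminus_offset Position within the excised circle that becomes
#'   position 0 of the linear genome.
#' @param id Id for the resulting record.
#' @return A linear `GenomeRecord` of length `att_right - att_left`.
#' @export
linearize_provirus <- function(host_segment, att_left, att_right,
                               terminus_offset = 0L, id = NULL) {
  stopifnot(inherits(host_segment, "GenomeRecord"))
  n <- host_segment$length_bp
  if (!(att_left >= 0 && att_left < att_right && att_right <= n)) {
    stop("att coordinates out of range: need 0 <= att_left < att_right <= ", n,
         call. = FALSE)
  }
  len <- att_right - att_left
  if (terminus_offset < 0 || terminus_offset >= len) {
    stop("terminus_offset out of range [0, ", len, ")", call. = FALSE)
  }
  circle <- substr(host_segment$sequence, att_left + 1L, att_right)
  lin <- if (terminus_offset == 0L) circle else {
    paste0(substr(circle, terminus_offset + 1L, len),
           substr(circle, 1L, terminus_offset))
  }
  genome_record(
    id %||% paste0(host_segment$id, "_provirus"),
    lin,
    description = sprintf("provirus excised %d..%d, opened at offset %d",
                          att_left, att_right, terminus_offset),
    topology = "linear"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
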