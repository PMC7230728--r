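#' Genome record
#'
#' A `GenomeRecord` bundles one genome sequence with its topology and (optional)
#' CDS annotations. It is the container every analysis in halomotif consumes.
#' Sequences are uppercase DNA over `{A,C,G,T,N}`; any other IUPAC ambiguity
#' code is collapsed to `N` on construction. Feature coordinates are stored
#' 0-based half-open internally; all user-facing reports are rendered 1-based
#' inclusive (the GenBank convention).
#'
#' @param id Accession or name.
#' @param sequence DNA string; case-folded to upper, ambiguity codes to `N`.
#' @param description Free-text description.
#' @param topology `"linear"` (virion genomes) or `"circular"` (e.g. a provirus
#'   circle before re-opening).
#' @param features A data frame of CDS features as returned by [cds_features()],
#'   or `NULL` for none.
#'
#' @return An object of class `GenomeRecord`: a list with elements `id`,
#'   `description`, `sequence`, `topology`, `features`, `length_bp`.
#' @seealso [cds_features()], [read_fasta()], [read_genbank()]
#' @export
#' @examples
#' g <- genome_record("toy", "acgtACGT")
#' g$length_bp
genome_record <- function(id, sequence, description = "",
                          topology = c("linear", "circular"),
                          features = NULL) {
  topology <- match.arg(topology)
  sequence <- .clean_dna(sequence)
  if (nchar(sequence) == 0L) {
    stop("GenomeRecord requires a non-empty sequence", call. = FALSE)
  }
  if (is.null(features)) features <- cds_features()
  rec <- structure(
    list(id = as.character(id), description = as.character(description),
         sequence = sequence, topology = topology, features = features,
         length_bp = nchar(sequence)),
    class = "GenomeRecord"
  )
  validate_genome_record(rec)
  rec
}

#' CDS feature table constructor
#'
#' Builds the feature table carried by a [genome_record()]. Coordinates are
#' 0-based half-open on the forward genomic strand (`start < end` always, also
#' for minus-strand features).
#'
#' @param locus_tag,start,end,strand,product,translation Parallel vectors; the
#'   translation is the amino-acid sequence without the stop, or `""`.
#' @return A data frame of class `cds_features`.
#' @export
cds_features <- function(locus_tag = character(), start = integer(),
                         end = integer(), strand = character(),
                         product = character(), translation = character()) {
  df <- data.frame(
    locus_tag = as.character(locus_tag),
    start = as.integer(start), end = as.integer(end),
    strand = as.character(strand),
    product = as.character(product),
    translation = as.character(translation),
    stringsAsFactors = FALSE
  )
  if (nrow(df) && !all(df$strand %in% c("+", "-"))) {
    stop("feature strand must be '+' or '-'", call. = FALSE)
  }
  if (any(df$start >= df$end)) {
    stop("feature start must be < end (0-based half-open)", call. = FALSE)
  }
  class(df) <- c("cds_features", "data.frame")
  df
}

#' Validate a GenomeRecord
#'
#' Checks the class invariants: alphabet, positive length, feature intervals
#' inside the sequence, translation length consistent with the CDS span.
#'
#' @param rec A `GenomeRecord`.
#' @return `rec`, invisibly; stops on violation.
#' @export
validate_genome_record <- function(rec) {
  stopifnot(inherits(rec, "GenomeRecord"))
  if (rec$length_bp != nchar(rec$sequence) || rec$length_bp <= 0L) {
    stop("length_bp must equal the sequence length and be > 0", call. = FALSE)
  }
  if (grepl("[^ACGTN]", rec$sequence)) {
    stop("sequence contains characters outside {A,C,G,T,N}", call. = FALSE)
  }
  ft <- rec$features
  if (nrow(ft)) {
    if (any(ft$start < 0L) || any(ft$end > rec$length_bp)) {
      stop("feature interval outside [0, length_bp)", call. = FALSE)
    }
    has_tr <- nzchar(ft$translation)
    if (any(has_tr)) {
      aa <- nchar(ft$translation[has_tr])
      nt <- (ft$end - ft$start)[has_tr]
      # stop codon excluded from /translation; allow 1-residue slack
      if (any(abs(nt / 3 - 1 - aa) > 1)) {
        stop("translation length inconsistent with CDS span", call. = FALSE)
      }
    }
  }
  invisible(rec)
}

#' @export
print.GenomeRecord <- function(x, ...) {
  cat(sprintf("GenomeRecord %s: %s bp, %s, %d CDS\n", x$id,
              format(x$length_bp, big.mark = ","), x$topology,
              nrow(x$features)))
  if (nzchar(x$description)) cat(" ", x$description, "\n")
  invisible(x)
}

# uppercase, fold non-ACGT IUPAC codes to N, reject everything else
.clean_dna <- function(x) {
  x <- toupper(as.character(x))
  if (length(x) != 1L) stop("sequence must be a single string", call. = FALSE)
  bad <- gsub("[ACGTNRYSWKMBDHVU]", "", x)
  if (nzchar(bad)) {
    stop("invalid sequence characters: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ","), call. = FALSE)
  }
  gsub("[RYSWKMBDHVU]", "N", x)
}
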