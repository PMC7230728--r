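#' Genome summary table
#'
#' One row per genome with the headline statistics of a genome table:
#' length, G+C percent (one decimal), CDS count and terminal-direct-repeat
#' length.
#'
#' @param genomes List of `GenomeRecord`s.
#' @param min_tdr,max_mismatch Passed to [find_tdr()].
#' @return Data frame with columns `genome`, `length_bp`, `gc_pct`, `n_cds`,
#'   `tdr_bp`.
#' @export
genome_summary <- function(genomes, min_tdr = 20L, max_mismatch = 0L) {
  if (inherits(genomes, "GenomeRecord")) genomes <- list(genomes)
  do.call(rbind, lapply(genomes, function(g) {
    tdr <- if (g$topology == "linear") {
      find_tdr(g, min_len = min_tdr, max_mismatch = max_mismatch)$length_bp
    } else NA_integer_
    data.frame(genome = g$id, length_bp = g$length_bp,
               gc_pct = round(100 * gc_content(g), 1L),
               n_cds = nrow(g$features), tdr_bp = tdr,
               stringsAsFactors = FALSE)
  }))
}

#' Avoidance matrix for a fixed motif panel
#'
#' The classic under-represented-tetramer view: genomes as rows, a panel of
#' palindromic motifs as columns, cells holding the Markov odds ratio
#' (observed/expected). Raw odds are returned; [format_motif_matrix()]
#' renders the publication style (two decimals, `0` for absent motifs, `.`
#' for normal or near-normal frequencies).
#'
#' @param genomes List of `GenomeRecord`s.
#' @param motifs Motif panel (default the five palindromic tetramers
#'   classically scored in HF1-group genomes).
#' @param null_model,under_threshold Passed to [motif_odds()].
#' @return Data frame: first column `genome`, one numeric column per motif
#'   (raw odds; 0 when absent).
#' @export
motif_odds_matrix <- function(genomes,
                              motifs = c("CTAG", "GATC", "AGCT", "TGCA",
                                         "CATG"),
                              null_model = "maximal_order",
                              under_threshold = 0.78) {
  if (inherits(genomes, "GenomeRecord")) genomes <- list(genomes)
  rows <- lapply(genomes, function(g) {
    vals <- lapply(motifs, function(m) {
      r <- motif_odds(g, m, null_model = null_model,
                      under_threshold = under_threshold)
      if (r$observed == 0L) 0 else r$odds
    })
    df <- data.frame(genome = g$id, stringsAsFactors = FALSE)
    df[motifs] <- vals
    df
  })
  do.call(rbind, rows)
}

#' Render an avoidance matrix in publication style
#'
#' @param mat Output of [motif_odds_matrix()].
#' @param under_threshold Odds at or above which a cell prints `"."`
#'   (normal or near-normal frequency).
#' @return Character data frame: `"0"` for absent, `"."` for normal,
#'   otherwise the odds to two decimals.
#' @export
format_motif_matrix <- function(mat, under_threshold = 0.78) {
  out <- mat
  for (cn in setdiff(names(mat), "genome")) {
    v <- mat[[cn]]
    out[[cn]] <- ifelse(v == 0, "0",
                        ifelse(v >= under_threshold, ".",
                               sprintf("%.2f", v)))
  }
  out
}

#' Replay the published isolate analyses from local accession files
#'
#' Recomputes the comparative statistics of the seven HF1-group virus
#' isolates from their deposited sequences: the avoidance matrix over the
#' CTAG/GATC/AGCT/TGCA/CATG panel, terminal-direct-repeat lengths, genome
#' summaries, and (when annotated GenBank files are present) CxxC censuses.
#' Sequences are read from `dir`, which must contain
#' `<accession>.fasta` files fetched beforehand (see
#' `scripts/fetch_accessions.R`; the package itself never touches the
#' network).
#'
#' @param dir Directory of accession FASTA (and optional `.gbk`) files.
#' @param accessions Named character vector mapping display names to
#'   accession file stems.
#' @return List with `summary`, `odds`, `odds_formatted`, `tdr`, and `cxxc`
#'   (possibly empty list).
#' @export
replay_isolates <- function(dir,
                            accessions = c(HF1 = "AY190604.2",
                                           HF2 = "AF222060.2",
                                           Hardycor2 = "MN901520",
                                           Serpecor1 = "MN901521",
                                           `HRTV-5` = "KC292022.1",
                                           `HRTV-8` = "KC292020.1",
                                           `HRTV-7` = "KC292021.1")) {
  paths <- file.path(dir, paste0(accessions, ".fasta"))
  missing <- !file.exists(paths)
  if (any(missing)) {
    stop("missing accession files: ",
         paste(basename(paths[missing]), collapse = ", "),
         " (run scripts/fetch_accessions.R first)", call. = FALSE)
  }
  genomes <- lapply(seq_along(paths), function(i) {
    g <- read_fasta(paths[i])[[1L]]
    g$id <- names(accessions)[i]
    g
  })
  cxxc <- list()
  gbk_paths <- file.path(dir, paste0(accessions, ".gbk"))
  for (i in which(file.exists(gbk_paths))) {
    rec <- read_genbank(gbk_paths[i])[[1L]]
    cxxc[[names(accessions)[i]]] <- cxxc_census(rec)
  }
  odds <- motif_odds_matrix(genomes)
  list(summary = genome_summary(genomes, min_tdr = 50L),
       odds = odds, odds_formatted = format_motif_matrix(odds),
       tdr = tdr_report(genomes, min_len = 50L),
       cxxc = cxxc)
}
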