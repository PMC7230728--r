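#' Exact-seed anchor matches between two genomes
#'
#' Finds shared exact k-mers between genome `a` and both strands of genome
#' `b`, merges co-diagonal seeds, and extends each merged seed without gaps
#' under an X-drop rule (match +1, mismatch -2, stop when the running score
#' falls `xdrop` below its maximum). Anchors shorter than `min_extend_len`
#' are discarded. Highly repetitive seeds (a k-mer occurring more than
#' `max_occ` times in `b`) are masked, the usual guard against quadratic
#' blow-up on low-complexity sequence.
#'
#' Coordinates in the result are 0-based half-open on the forward strands of
#' `a` and `b`; for minus-strand anchors `s_start/s_end` still refer to the
#' forward strand of `b`.
#'
#' @param a,b `GenomeRecord`s (or DNA strings).
#' @param k Seed length in `[8, 32]` (default 14).
#' @param min_extend_len Minimum anchor length kept (default 30).
#' @param xdrop X-drop threshold in match-score units (default 20).
#' @param max_occ Seed occurrence cap in `b` (default 64).
#' @return Data frame of class `anchor_matches` with columns `q_start`,
#'   `q_end`, `s_start`, `s_end`, `strand`, `matches`, `length`, sorted by
#'   `q_start`; attributes `query`, `subject`, `query_length`,
#'   `subject_length`.
#' @export
seed_matches <- function(a, b, k = 14L, min_extend_len = 30L, xdrop = 20L,
                         max_occ = 64L) {
  if (is.character(a)) a <- genome_record("query", a)
  if (is.character(b)) b <- genome_record("subject", b)
  if (k < 8L || k > 32L) stop("seed length k must be in [8, 32]", call. = FALSE)
  nb <- b$length_bp
  out <- list()
  for (strand in c("+", "-")) {
    bseq <- if (strand == "+") b$sequence else reverse_complement(b$sequence)
    anc <- .strand_anchors(a$sequence, bseq, k, min_extend_len, xdrop, max_occ)
    if (is.null(anc) || !nrow(anc)) next
    anc$strand <- strand
    if (strand == "-") {
      s0 <- nb - anc$s_end
      anc$s_end <- nb - anc$s_start
      anc$s_start <- s0
    }
    out[[length(out) + 1L]] <- anc
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(q_start = integer(), q_end = integer(), s_start = integer(),
               s_end = integer(), strand = character(), matches = integer(),
               length = integer(), stringsAsFactors = FALSE)
  res <- res[order(res$q_start, res$s_start), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "query") <- a$id
  attr(res, "subject") <- b$id
  attr(res, "query_length") <- a$length_bp
  attr(res, "subject_length") <- nb
  class(res) <- c("anchor_matches", "data.frame")
  res
}

# anchors of aseq vs one strand of b, coordinates 0-based half-open in
# (aseq, bseq) space
.strand_anchors <- function(aseq, bseq, k, min_extend_len, xdrop, max_occ) {
  na <- nchar(aseq); nb <- nchar(bseq)
  if (na < k || nb < k) return(NULL)
  ka <- substring(aseq, 1:(na - k + 1L), k:na)
  kb <- substring(bseq, 1:(nb - k + 1L), k:nb)
  ok_b <- !grepl("N", kb, fixed = TRUE)
  idx <- split(which(ok_b), kb[ok_b])
  idx <- idx[lengths(idx) <= max_occ]
  hit <- idx[match(ka, names(idx))]
  n_hit <- lengths(hit)
  n_hit[grepl("N", ka, fixed = TRUE)] <- 0L
  if (sum(n_hit) == 0L) return(NULL)
  i <- rep.int(seq_along(ka), n_hit)          # 1-based window starts in a
  j <- unlist(hit[n_hit > 0L], use.names = FALSE)
  d <- j - i
  ord <- order(d, i)
  d <- d[ord]; i <- i[ord]
  m <- length(i)
  merge_gap <- max(k, 16L)
  new_run <- c(TRUE, d[-1L] != d[-m] | i[-1L] - i[-m] > merge_gap)
  i0 <- i[new_run]
  last <- c(new_run[-1L], TRUE)
  i1 <- i[last]
  d0 <- d[new_run]
  ra <- charToRaw(aseq); rb <- charToRaw(bseq)
  anchors <- data.frame(q_start = i0 - 1L, q_end = i1 + k - 1L,
                        s_start = i0 - 1L + d0, s_end = i1 + k - 1L + d0)
  # ungapped X-drop extension on both ends
  for (r in seq_len(nrow(anchors))) {
    qs <- anchors$q_start[r]; qe <- anchors$q_end[r]
    ss <- anchors$s_start[r]
    # left
    sc <- 0; bestsc <- 0; bestext <- 0L; ext <- 0L
    while (qs - ext > 0L && ss - ext > 0L) {
      ext <- ext + 1L
      sc <- sc + if (ra[qs - ext + 1L] == rb[ss - ext + 1L]) 1 else -2
      if (sc > bestsc) { bestsc <- sc; bestext <- ext }
      if (bestsc - sc > xdrop) break
    }
    anchors$q_start[r] <- qs - bestext
    anchors$s_start[r] <- ss - bestext
    # right
    se <- anchors$s_end[r]
    sc <- 0; bestsc <- 0; bestext <- 0L; ext <- 0L
    while (qe + ext < length(ra) && se + ext < length(rb)) {
      ext <- ext + 1L
      sc <- sc + if (ra[qe + ext] == rb[se + ext]) 1 else -2
      if (sc > bestsc) { bestsc <- sc; bestext <- ext }
      if (bestsc - sc > xdrop) break
    }
    anchors$q_end[r] <- qe + bestext
    anchors$s_end[r] <- se + bestext
  }
  # extension can make co-diagonal anchors overlap; merge them
  diag0 <- anchors$s_start - anchors$q_start
  ord <- order(diag0, anchors$q_start)
  anchors <- anchors[ord, , drop = FALSE]
  diag0 <- diag0[ord]
  keep_new <- c(TRUE, diag0[-1L] != diag0[-length(diag0)] |
                  anchors$q_start[-1L] > anchors$q_end[-nrow(anchors)])
  grp <- cumsum(keep_new)
  anchors <- data.frame(
    q_start = tapply(anchors$q_start, grp, min),
    q_end = tapply(anchors$q_end, grp, max),
    s_start = tapply(anchors$s_start, grp, min),
    s_end = tapply(anchors$s_end, grp, max))
  anchors$length <- anchors$q_end - anchors$q_start
  anchors <- anchors[anchors$length >= min_extend_len, , drop = FALSE]
  if (!nrow(anchors)) return(NULL)
  anchors$matches <- vapply(seq_len(nrow(anchors)), function(r) {
    sum(ra[(anchors$q_start[r] + 1L):anchors$q_end[r]] ==
          rb[(anchors$s_start[r] + 1L):anchors$s_end[r]])
  }, 0L)
  rownames(anchors) <- NULL
  anchors
}

#' Pairwise whole-genome nucleotide identity
#'
#' Seed-and-chain identity estimate for a genome pair: exact-seed anchors
#' ([seed_matches()]) are chained by a weighted longest-increasing-
#' subsequence over the strand with the heavier chain, inter-anchor gaps up
#' to `gap_cap` are closed by dynamic-programming global alignment, larger
#' gaps (and one-sided gaps) contribute unaligned columns of length
#' `max(gap_a, gap_b)`, and identity is counted as identical columns over
#' all alignment columns including gap columns — approximating the
#' percent-identical-nucleotides-after-multiple-alignment convention of
#' whole-genome comparisons. Terminal overhangs follow the same gap rule.
#'
#' @inheritParams seed_matches
#' @param gap_cap Largest inter-anchor gap closed by alignment (default
#'   5000 bp).
#' @param gap_opening,gap_extension Gap penalties of the closure aligner.
#' @return An `IdentityResult`: list with `pct_identity` in `[0,100]`,
#'   `aligned_columns`, `identical_columns`, `coverage_fraction`, `strand`,
#'   `n_anchors`.
#' @export
pairwise_identity <- function(a, b, k = 14L, min_extend_len = 30L,
                              xdrop = 20L, max_occ = 64L, gap_cap = 5000L,
                              gap_opening = 5, gap_extension = 2) {
  if (is.character(a)) a <- genome_record("query", a)
  if (is.character(b)) b <- genome_record("subject", b)
  if (a$topology != "linear" || b$topology != "linear") {
    stop("pairwise_identity requires linear genomes", call. = FALSE)
  }
  na <- a$length_bp; nb <- b$length_bp
  empty <- structure(
    list(pct_identity = 0, aligned_columns = 0L, identical_columns = 0L,
         coverage_fraction = 0, strand = NA_character_, n_anchors = 0L,
         query = a$id, subject = b$id),
    class = "IdentityResult")

  best <- NULL
  for (strand in c("+", "-")) {
    bseq <- if (strand == "+") b$sequence else reverse_complement(b$sequence)
    anc <- .strand_anchors(a$sequence, bseq, k, min_extend_len, xdrop,
                           max_occ)
    if (is.null(anc) || !nrow(anc)) next
    ch <- .chain_anchors(anc)
    if (is.null(best) || ch$score > best$score) {
      best <- list(score = ch$score, chain = anc[ch$path, , drop = FALSE],
                   strand = strand, bseq = bseq)
    }
  }
  if (is.null(best)) return(empty)
  chain <- .trim_chain(best$chain, a$sequence, best$bseq)
  ident <- sum(chain$matches)
  cols <- sum(chain$length)
  gq <- c(chain$q_start[1L],
          chain$q_start[-1L] - chain$q_end[-nrow(chain)],
          na - chain$q_end[nrow(chain)])
  gs <- c(chain$s_start[1L],
          chain$s_start[-1L] - chain$s_end[-nrow(chain)],
          nchar(best$bseq) - chain$s_end[nrow(chain)])
  qpos <- c(chain$q_start, na); spos <- c(chain$s_start, nchar(best$bseq))
  for (g in seq_along(gq)) {
    ga <- gq[g]; gb <- gs[g]
    if (ga == 0L && gb == 0L) next
    if (ga == 0L || gb == 0L || max(ga, gb) > gap_cap) {
      cols <- cols + max(ga, gb)
      next
    }
    qa <- substr(a$sequence, qpos[g] - ga + 1L, qpos[g])
    sb <- substr(best$bseq, spos[g] - gb + 1L, spos[g])
    aln <- Biostrings::pairwiseAlignment(
      qa, sb, type = "global",
      substitutionMatrix = .nuc_submat(),
      gapOpening = gap_opening, gapExtension = gap_extension)
    cols <- cols + Biostrings::nchar(aln)
    ident <- ident + Biostrings::nmatch(aln)
  }
  structure(
    list(pct_identity = 100 * ident / cols,
         aligned_columns = as.integer(cols),
         identical_columns = as.integer(ident),
         coverage_fraction = min(1, (chain$q_end[nrow(chain)] -
                                       chain$q_start[1L]) / na),
         strand = best$strand, n_anchors = nrow(chain),
         query = a$id, subject = b$id),
    class = "IdentityResult")
}

#' @export
print.IdentityResult <- function(x, ...) {
  cat(sprintf(
    "IdentityResult %s vs %s: %.1f%% identity (%d/%d columns, coverage %.2f, strand %s, %d anchors)\n",
    x$query, x$subject, x$pct_identity, x$identical_columns,
    x$aligned_columns, x$coverage_fraction,
    if (is.na(x$strand)) "-" else x$strand, x$n_anchors))
  invisible(x)
}

.nuc_submat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                           baseOnly = FALSE)
}

# weighted collinear chaining (LIS on anchor starts, weight = match count,
# overlap trimmed at cost 1/column, small penalty on diagonal shift)
.chain_anchors <- function(anc) {
  m <- nrow(anc)
  o <- order(anc$q_start, anc$s_start)
  anc <- anc[o, , drop = FALSE]
  score <- as.numeric(anc$matches)
  prev <- rep(NA_integer_, m)
  for (i in seq_len(m)[-1L]) {
    js <- seq_len(i - 1L)
    ok <- anc$s_start[js] < anc$s_start[i]
    if (!any(ok)) next
    js <- js[ok]
    oq <- anc$q_end[js] - anc$q_start[i]
    os <- anc$s_end[js] - anc$s_start[i]
    ov <- pmax(0L, pmax(oq, os))
    gap_q <- anc$q_start[i] - anc$q_end[js]
    gap_s <- anc$s_start[i] - anc$s_end[js]
    cand <- score[js] + anc$matches[i] - ov -
      0.001 * abs(gap_q - gap_s)
    feasible <- ov < anc$length[i]
    cand[!feasible] <- -Inf
    bi <- which.max(cand)
    if (cand[bi] > score[i]) {
      score[i] <- cand[bi]
      prev[i] <- js[bi]
    }
  }
  end <- which.max(score)
  path <- end
  while (!is.na(prev[path[1L]])) path <- c(prev[path[1L]], path)
  list(score = score[end], path = o[path])
}

# physically trim chain overlaps (diagonal trim from the left side of the
# later anchor) and recompute match counts
.trim_chain <- function(chain, aseq, bseq) {
  ra <- charToRaw(aseq); rb <- charToRaw(bseq)
  for (i in seq_len(nrow(chain))[-1L]) {
    t <- max(chain$q_end[i - 1L] - chain$q_start[i],
             chain$s_end[i - 1L] - chain$s_start[i], 0L)
    if (t > 0L) {
      chain$q_start[i] <- chain$q_start[i] + t
      chain$s_start[i] <- chain$s_start[i] + t
    }
  }
  keep <- chain$q_end > chain$q_start & chain$s_end > chain$s_start
  chain <- chain[keep, , drop = FALSE]
  chain$length <- chain$q_end - chain$q_start
  chain$matches <- vapply(seq_len(nrow(chain)), function(r) {
    sum(ra[(chain$q_start[r] + 1L):chain$q_end[r]] ==
          rb[(chain$s_start[r] + 1L):chain$s_end[r]])
  }, 0L)
  chain
}

#' Export anchor matches as PAF-style TSV
#'
#' Writes one row per anchor (query, q_start, q_end, strand, subject,
#' s_start, s_end, matches, length), sorted by `q_start`, with a header —
#' ready for dot-plot rendering.
#'
#' @param matches An `anchor_matches` data frame from [seed_matches()].
#' @param path Output TSV file.
#' @return `path`, invisibly.
#' @export
dotplot_export <- function(matches, path) {
  stopifnot(inherits(matches, "anchor_matches"))
  df <- data.frame(
    query = rep(attr(matches, "query") %||% "query",
                length.out = nrow(matches)),
    q_start = matches$q_start, q_end = matches$q_end,
    strand = matches$strand,
    subject = rep(attr(matches, "subject") %||% "subject",
                  length.out = nrow(matches)),
    s_start = matches$s_start, s_end = matches$s_end,
    matches = matches$matches, length = matches$length,
    stringsAsFactors = FALSE)
  df <- df[order(df$q_start), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
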