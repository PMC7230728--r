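#' Read GenBank flat files
#'
#' Parses one or more records from a GenBank flat file (LOCUS / FEATURES /
#' ORIGIN sections). CDS features are captured with `locus_tag`, `product`
#' and the `/translation` qualifier verbatim when present; GenBank 1-based
#' inclusive locations are converted to the internal 0-based half-open
#' convention. `complement(...)` sets the minus strand; a `join(...)` location
#' is stored by its outer span (sufficient for the census and density
#' analyses, which work from translations).
#'
#' @param path GenBank flat file.
#' @return List of [genome_record()] objects.
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  # split into records at '//'
  ends <- grep("^//\\s*$", lines)
  if (!length(ends)) {
    if (!any(nzchar(trimws(lines)))) return(list())
    stop("malformed GenBank file (no '//' record terminator): ", path,
         call. = FALSE)
  }
  starts <- c(1L, head(ends, -1L) + 1L)
  recs <- list()
  for (r in seq_along(ends)) {
    chunk <- lines[starts[r]:(ends[r] - 1L)]
    if (!any(nzchar(trimws(chunk)))) next
    recs[[length(recs) + 1L]] <- .parse_genbank_record(chunk, path)
  }
  recs
}

.parse_genbank_record <- function(lines, path) {
  locus_i <- grep("^LOCUS", lines)
  if (!length(locus_i)) stop("GenBank record without LOCUS line in ", path,
                             call. = FALSE)
  locus <- strsplit(trimws(lines[locus_i[1L]]), "\\s+")[[1L]]
  id <- if (length(locus) >= 2L) locus[2L] else "unnamed"
  topology <- if (any(tolower(locus) == "circular")) "circular" else "linear"
  def_i <- grep("^DEFINITION", lines)
  description <- if (length(def_i)) {
    sub("^DEFINITION\\s+", "", lines[def_i[1L]])
  } else ""

  origin_i <- grep("^ORIGIN", lines)
  if (!length(origin_i)) {
    stop("GenBank record '", id, "' has no ORIGIN sequence", call. = FALSE)
  }
  seq_lines <- lines[(origin_i[1L] + 1L):length(lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(sequence)) {
    stop("GenBank record '", id, "' has an empty ORIGIN sequence",
         call. = FALSE)
  }

  feat_i <- grep("^FEATURES", lines)
  features <- cds_features()
  if (length(feat_i)) {
    fl <- lines[(feat_i[1L] + 1L):(origin_i[1L] - 1L)]
    features <- .parse_genbank_features(fl, id, nchar(sequence))
  }
  genome_record(id, sequence, description = description, topology = topology,
                features = features)
}

.parse_genbank_features <- function(fl, id, seq_len) {
  # a new feature starts with a key in columns 6-20; qualifier/location
  # continuations are indented to column 22
  key_re <- "^ {5}(\\S+)\\s+(.*)$"
  is_key <- grepl(key_re, fl) & !grepl("^ {21}", fl)
  idx <- which(is_key)
  out <- list()
  for (j in seq_along(idx)) {
    first <- idx[j]
    last <- if (j < length(idx)) idx[j + 1L] - 1L else length(fl)
    key <- sub(key_re, "\\1", fl[first])
    if (key != "CDS") next
    body <- c(sub(key_re, "\\2", fl[first]), trimws(fl[(first + 1L):last]))
    if (first == last) body <- body[1L]
    # location: everything up to the first qualifier line
    qual_start <- grep("^/", body)
    loc <- paste(body[seq_len(if (length(qual_start)) qual_start[1L] - 1L
                              else length(body))], collapse = "")
    loc <- gsub("\\s", "", loc)
    strand <- if (grepl("complement", loc)) "-" else "+"
    nums <- as.numeric(regmatches(loc, gregexpr("[0-9]+", loc))[[1L]])
    if (length(nums) < 2L) {
      stop("unsupported CDS location '", loc, "' in record ", id,
           call. = FALSE)
    }
    start1 <- min(nums); end1 <- max(nums)
    if (end1 > seq_len) {
      stop("CDS feature ", start1, "..", end1, " extends past sequence end (",
           seq_len, ") in record ", id, call. = FALSE)
    }
    quals <- .parse_qualifiers(body)
    out[[length(out) + 1L]] <- data.frame(
      locus_tag = quals[["locus_tag"]] %||% "",
      start = as.integer(start1 - 1L), end = as.integer(end1),
      strand = strand,
      product = quals[["product"]] %||% "",
      translation = quals[["translation"]] %||% "",
      stringsAsFactors = FALSE
    )
  }
  if (!length(out)) return(cds_features())
  df <- do.call(rbind, out)
  class(df) <- c("cds_features", "data.frame")
  df
}

# collapse multi-line qualifiers, strip quotes
.parse_qualifiers <- function(body) {
  starts <- grep("^/", body)
  quals <- list()
  for (i in seq_along(starts)) {
    from <- starts[i]
    to <- if (i < length(starts)) starts[i + 1L] - 1L else length(body)
    txt <- paste(body[from:to], collapse = if (grepl("^/translation",
                                                     body[from])) "" else " ")
    m <- regmatches(txt, regexec('^/([A-Za-z_]+)=?"?([^"]*)"?', txt))[[1L]]
    if (length(m) == 3L) quals[[m[2L]]] <- m[3L]
  }
  quals
}

#' Write a GenBank flat file
#'
#' Emits a minimal GenBank flat file (LOCUS, DEFINITION, FEATURES with source
#' and CDS entries, ORIGIN) that [read_genbank()] parses back to an equal
#' record. Output is byte-stable: no timestamps or environment-dependent
#' content.
#'
#' @param record A `GenomeRecord`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(record, path) {
  stopifnot(inherits(record, "GenomeRecord"))
  validate_genome_record(record)
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("LOCUS       %s %d bp    DNA     %s   UNA", record$id, record$length_bp,
    record$topology)
  if (nzchar(record$description)) w("DEFINITION  %s", record$description)
  w("FEATURES             Location/Qualifiers")
  w("     source          1..%d", record$length_bp)
  ft <- record$features
  for (i in seq_len(nrow(ft))) {
    loc <- sprintf("%d..%d", ft$start[i] + 1L, ft$end[i])
    if (ft$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
    w("     CDS             %s", loc)
    if (nzchar(ft$locus_tag[i])) {
      w("                     /locus_tag=\"%s\"", ft$locus_tag[i])
    }
    if (nzchar(ft$product[i])) {
      w("                     /product=\"%s\"", ft$product[i])
    }
    if (nzchar(ft$translation[i])) {
      tr <- paste0("/translation=\"", ft$translation[i], "\"")
      first_w <- 58L
      pieces <- character()
      pieces <- c(pieces, substr(tr, 1L, first_w))
      rest <- substring(tr, first_w + 1L)
      while (nzchar(rest)) {
        pieces <- c(pieces, substr(rest, 1L, 58L))
        rest <- substring(rest, 59L)
      }
      writeLines(paste0(strrep(" ", 21L), pieces), con)
    }
  }
  w("ORIGIN")
  seq <- tolower(record$sequence)
  pos <- seq(1L, record$length_bp, by = 60L)
  for (p in pos) {
    blk_starts <- seq(p, min(p + 59L, record$length_bp), by = 10L)
    blocks <- substring(seq, blk_starts,
                        pmin(blk_starts + 9L, record$length_bp))
    w("%9d %s", p, paste(blocks, collapse = " "))
  }
  w("//")
  invisible(path)
}
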