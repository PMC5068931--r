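# Tabular alignment hit tables (the 12-column tab-separated dialect emitted
# by BLAST-style tools with tabular output: query, subject, %identity,
# alignment length, mismatches, gap opens, qstart, qend, sstart, send,
# evalue, bitscore).

HIT_COLS <- c("query_id", "subject_id", "pct_identity", "aln_length",
              "mismatches", "gap_opens", "q_start", "q_end",
              "s_start", "s_end", "evalue", "bitscore")

#' Read a 12-column tabular alignment hit table
#'
#' Parses the standard tab-separated hit format (no header, `#` comment lines
#' permitted). Coordinates are kept as read: 1-based inclusive, with reverse
#' subject orientation encoded by `s_start > s_end`.
#'
#' @param path path to the tab-separated file.
#' @return a tibble with one row per hit, columns
#'   `r paste(HIT_COLS, collapse = ", ")`, row order preserved.
#' @seealso [normalize_hits()] for the 0-based half-open forward-strand view
#'   every downstream computation uses.
#' @export
read_hits_table <- function(path) {
  if (!file.exists(path)) stop("hit table not found: ", path)
  lines <- readr::read_lines(path)
  keep <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  if (length(keep) == 0) {
    return(tibble(
      query_id = character(), subject_id = character(),
      pct_identity = double(), aln_length = integer(),
      mismatches = integer(), gap_opens = integer(),
      q_start = integer(), q_end = integer(),
      s_start = integer(), s_end = integer(),
      evalue = double(), bitscore = double()
    ))
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12)) {
    i <- which(nf != 12)[1]
    stop("expected 12 tab-separated columns but found ", nf[i],
         " at line ", keep[i])
  }
  m <- do.call(rbind, fields)
  num <- suppressWarnings(apply(m[, 3:12, drop = FALSE], 2, as.numeric))
  num <- matrix(num, ncol = 10)
  if (anyNA(num)) {
    bad <- which(apply(num, 1, anyNA))[1]
    stop("unparsable numeric field at line ", keep[bad])
  }
  hits <- tibble(
    query_id = m[, 1], subject_id = m[, 2],
    pct_identity = num[, 1], aln_length = as.integer(num[, 2]),
    mismatches = as.integer(num[, 3]), gap_opens = as.integer(num[, 4]),
    q_start = as.integer(num[, 5]), q_end = as.integer(num[, 6]),
    s_start = as.integer(num[, 7]), s_end = as.integer(num[, 8]),
    evalue = num[, 9], bitscore = num[, 10]
  )
  validate_hits(hits)
  hits
}

validate_hits <- function(hits) {
  stopifnot(all(HIT_COLS %in% names(hits)))
  if (any(hits$pct_identity < 0 | hits$pct_identity > 100)) {
    stop("pct_identity outside [0,100]")
  }
  if (any(hits$q_start > hits$q_end)) {
    stop("q_start > q_end; query coordinates must be forward")
  }
  if (any(hits$evalue < 0) || any(hits$bitscore < 0)) {
    stop("negative evalue or bitscore")
  }
  invisible(hits)
}

#' Normalize hit coordinates to 0-based half-open forward-strand intervals
#'
#' The single place where the 1-based inclusive tabular convention is
#' converted. Adds columns `q_lo`/`q_hi` (query) and `s_lo`/`s_hi` (subject),
#' all 0-based half-open on the forward strand, plus `s_strand`
#' (`"+"`/`"-"`, from the original `s_start`/`s_end` order).
#'
#' @param hits a hit tibble as returned by [read_hits_table()].
#' @param ref_lengths optional named vector (or two-column tibble) of subject
#'   lengths; when supplied, hits extending beyond a subject are an error.
#' @return `hits` with the normalized interval columns appended.
#' @export
normalize_hits <- function(hits, ref_lengths = NULL) {
  validate_hits(hits)
  rev <- hits$s_start > hits$s_end
  out <- mutate(hits,
    q_lo = .data$q_start - 1L, q_hi = .data$q_end,
    s_lo = ifelse(rev, .data$s_end, .data$s_start) - 1L,
    s_hi = ifelse(rev, .data$s_start, .data$s_end),
    s_strand = ifelse(rev, "-", "+")
  )
  if (!is.null(ref_lengths)) {
    rl <- as_ref_lengths(ref_lengths)
    unknown <- setdiff(out$subject_id, names(rl))
    if (length(unknown)) {
      stop("subject(s) missing from ref_lengths: ",
           paste(head(unknown, 5), collapse = ", "))
    }
    over <- out$s_hi > rl[out$subject_id]
    if (any(over)) {
      i <- which(over)[1]
      stop("hit beyond subject length: ", out$query_id[i], " vs ",
           out$subject_id[i], " ends at ", out$s_hi[i], " > ",
           rl[out$subject_id[i]])
    }
  }
  out
}

# Accept a named numeric vector, or a data frame whose first two columns are
# id and length, and return a named numeric vector.
as_ref_lengths <- function(x) {
  if (is.data.frame(x)) {
    out <- setNames(as.numeric(x[[2]]), as.character(x[[1]]))
  } else {
    stopifnot(!is.null(names(x)))
    out <- setNames(as.numeric(x), names(x))
  }
  if (anyDuplicated(names(out))) stop("duplicate reference ids in lengths")
  if (any(out <= 0)) stop("non-positive reference length")
  out
}

#' Write hits in the 12-column tabular format
#'
#' @param hits hit tibble (normalized columns, if present, are dropped).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hits_table <- function(hits, path) {
  validate_hits(hits)
  readr::write_tsv(hits[HIT_COLS], path, col_names = FALSE)
  invisible(path)
}
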