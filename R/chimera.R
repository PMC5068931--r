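# Chimeric-contig detection from translated-search hit tables. A contig is
# trans-chimeric when disjoint parts of it match different reference
# subjects, self-chimeric when disjoint parts re-match the same subject
# region (tandem join) or match it in opposite orientations (inverted join).
# Query intervals are in contig (nucleotide) units; cuts happen on the
# contig.

#' Chimera-scan parameters
#'
#' @param min_identity minimum percent identity for a hit to contribute
#'   (default 30, permissive enough for cross-species protein hits).
#' @param min_seg_len minimum alignment length in query units (default 100).
#' @param max_q_overlap maximum query overlap, in query units, for two
#'   segments to count as disjoint evidence (default 60).
#' @param min_self_overlap minimum mutual subject-overlap fraction for two
#'   same-subject segments to indicate a tandem self-join (default 0.2).
#' @return a named list of thresholds.
#' @export
chimera_params <- function(min_identity = 30, min_seg_len = 100,
                           max_q_overlap = 60, min_self_overlap = 0.2) {
  stopifnot(min_identity >= 0, min_identity <= 100, min_seg_len >= 1,
            max_q_overlap >= 0, min_self_overlap > 0, min_self_overlap <= 1)
  list(min_identity = min_identity, min_seg_len = min_seg_len,
       max_q_overlap = max_q_overlap, min_self_overlap = min_self_overlap)
}

# Chain collinear same-subject hits of one contig into segments. Hits are
# collinear when the subject interval progresses with the query in the
# orientation's direction, allowing up to `tol` units of subject overlap.
chain_segments <- function(h, tol) {
  h <- arrange(h, .data$q_lo, .data$q_hi)
  seg_id <- integer(nrow(h))
  cur <- 1L
  seg_id[1] <- cur
  s_lo <- h$s_lo[1]; s_hi <- h$s_hi[1]
  for (k in seq_len(nrow(h))[-1]) {
    ok <- if (h$s_strand[k] == "+") {
      h$s_lo[k] >= s_hi - tol && h$s_hi[k] >= s_hi
    } else {
      h$s_hi[k] <= s_lo + tol && h$s_lo[k] <= s_lo
    }
    if (!ok) {
      cur <- cur + 1L
      s_lo <- h$s_lo[k]; s_hi <- h$s_hi[k]
    } else {
      s_lo <- min(s_lo, h$s_lo[k]); s_hi <- max(s_hi, h$s_hi[k])
    }
    seg_id[k] <- cur
  }
  h |>
    mutate(seg = seg_id) |>
    group_by(.data$seg) |>
    summarise(q_lo = min(.data$q_lo), q_hi = max(.data$q_hi),
              s_lo = min(.data$s_lo), s_hi = max(.data$s_hi),
              n_hits = n(), .groups = "drop") |>
    select(-"seg")
}

#' Collapse one contig's hits into alignment segments
#'
#' Filters hits by identity and alignment length, then merges hits to the
#' same subject with compatible orientation and a consistent diagonal into
#' segments. Pairs of segments overlapping by more than `max_q_overlap` on
#' the query are recorded in the `conflicts` attribute.
#'
#' @param contig_hits normalized hit tibble for a single query.
#' @param params a [chimera_params()] list.
#' @return segment tibble (`subject_id`, `orientation`, `q_lo`, `q_hi`,
#'   `s_lo`, `s_hi`, `n_hits`) ordered by query start, with attribute
#'   `conflicts`: tibble (`seg_i`, `seg_j`, `q_overlap`).
#' @export
segment_hits <- function(contig_hits, params = chimera_params()) {
  if (!all(c("q_lo", "s_lo") %in% names(contig_hits))) {
    contig_hits <- normalize_hits(contig_hits)
  }
  stopifnot(length(unique(contig_hits$query_id)) <= 1)
  h <- filter(contig_hits,
              .data$pct_identity >= params$min_identity,
              .data$aln_length >= params$min_seg_len)
  empty_conflicts <- tibble(seg_i = integer(), seg_j = integer(),
                            q_overlap = double())
  if (nrow(h) == 0) {
    segs <- tibble(subject_id = character(), orientation = character(),
                   q_lo = integer(), q_hi = integer(),
                   s_lo = integer(), s_hi = integer(), n_hits = integer())
    attr(segs, "conflicts") <- empty_conflicts
    return(segs)
  }
  segs <- h |>
    group_by(.data$subject_id, .data$s_strand) |>
    dplyr::group_modify(~chain_segments(.x, params$max_q_overlap),
                        .keep = TRUE) |>
    ungroup() |>
    select("subject_id", orientation = "s_strand", "q_lo", "q_hi",
           "s_lo", "s_hi", "n_hits") |>
    arrange(.data$q_lo, .data$q_hi)
  conflicts <- empty_conflicts
  if (nrow(segs) > 1) {
    cmb <- utils::combn(nrow(segs), 2)
    ov <- pmin(segs$q_hi[cmb[1, ]], segs$q_hi[cmb[2, ]]) -
      pmax(segs$q_lo[cmb[1, ]], segs$q_lo[cmb[2, ]])
    bad <- ov > params$max_q_overlap
    conflicts <- tibble(seg_i = cmb[1, bad], seg_j = cmb[2, bad],
                        q_overlap = ov[bad])
  }
  attr(segs, "conflicts") <- conflicts
  segs
}

# Is the ordered disjoint segment pair (a, b) evidence of a chimeric join?
offending_kind <- function(a, b, min_self_overlap) {
  if (a$subject_id != b$subject_id) return("trans")
  if (a$orientation != b$orientation) return("self")
  s_ov <- min(a$s_hi, b$s_hi) - max(a$s_lo, b$s_lo)
  min_len <- min(a$s_hi - a$s_lo, b$s_hi - b$s_lo)
  if (min_len > 0 && s_ov / min_len >= min_self_overlap) return("self")
  NA_character_
}

#' Detect chimeric contigs
#'
#' Scans each contig's segments (see [segment_hits()]) along the query.
#' Adjacent query-disjoint segments matching different subjects yield a
#' trans call; adjacent disjoint segments re-matching the same subject
#' region, or matching it in opposite orientations, yield a self call.
#' The breakpoint is the midpoint of the query gap between the offending
#' segments (0-based, cut before the position); a zero gap puts it at the
#' segment boundary. Contigs with a single segment, or a collinear
#' multi-HSP structure, are never called.
#'
#' @param hits hit tibble covering any number of contigs.
#' @param params a [chimera_params()] list.
#' @return tibble with one row per chimeric contig: `contig_id`, `kind`
#'   (`"trans"` if any cross-subject join, else `"self"`), `n_segments`,
#'   `breakpoints` (list column of 0-based cut positions) and `segments`
#'   (list column of segment tibbles).
#' @export
detect_chimeras <- function(hits, params = chimera_params()) {
  if (!all(c("q_lo", "s_lo") %in% names(hits))) hits <- normalize_hits(hits)
  # a single hit can never produce two segments; skip those contigs outright
  multi <- names(which(table(hits$query_id) >= 2))
  hits <- filter(hits, .data$query_id %in% multi)
  calls <- hits |>
    group_by(.data$query_id) |>
    dplyr::group_map(function(h, key) {
      segs <- segment_hits(mutate(h, query_id = key$query_id), params)
      if (nrow(segs) < 2) return(NULL)
      kinds <- character(0)
      bps <- integer(0)
      for (k in seq_len(nrow(segs) - 1)) {
        a <- segs[k, ]; b <- segs[k + 1, ]
        q_ov <- min(a$q_hi, b$q_hi) - max(a$q_lo, b$q_lo)
        if (q_ov > params$max_q_overlap) next
        kind <- offending_kind(a, b, params$min_self_overlap)
        if (is.na(kind)) next
        kinds <- c(kinds, kind)
        gap_lo <- min(a$q_hi, b$q_lo)
        bps <- c(bps, as.integer(floor((gap_lo + b$q_lo) / 2)))
      }
      if (length(kinds) == 0) return(NULL)
      tibble(contig_id = key$query_id,
             kind = if (any(kinds == "trans")) "trans" else "self",
             n_segments = nrow(segs),
             breakpoints = list(unique(bps)),
             segments = list(segs))
    }) |>
    purrr::compact() |>
    bind_rows()
  if (nrow(calls) == 0) {
    calls <- tibble(contig_id = character(), kind = character(),
                    n_segments = integer(), breakpoints = list(),
                    segments = list())
  }
  calls
}

#' Cut called chimeras into their pieces
#'
#' Each called contig is replaced, in place, by its pieces (ids suffixed
#' `_part1..k` in 5'-to-3' order). Total bases are conserved; uncalled
#' contigs are untouched.
#'
#' @param seqs sequence tibble containing every called contig.
#' @param calls a [detect_chimeras()] tibble.
#' @return the cut sequence tibble.
#' @export
cut_chimeras <- function(seqs, calls) {
  if (nrow(calls) == 0) return(seqs)
  missing <- setdiff(calls$contig_id, seqs$id)
  if (length(missing)) {
    stop("called contig(s) absent from the sequence set: ",
         paste(missing, collapse = ", "))
  }
  lens <- setNames(nchar(seqs$sequence), seqs$id)
  for (k in seq_len(nrow(calls))) {
    bp <- calls$breakpoints[[k]]
    if (any(bp <= 0 | bp >= lens[[calls$contig_id[k]]])) {
      stop("breakpoint outside contig ", calls$contig_id[k])
    }
  }
  pieces <- purrr::map(seq_len(nrow(seqs)), function(i) {
    id <- seqs$id[i]
    sequence <- seqs$sequence[i]
    k <- match(id, calls$contig_id)
    if (is.na(k)) return(seqs[i, , drop = FALSE])
    bp <- sort(unique(calls$breakpoints[[k]]))
    lo <- c(0L, bp); hi <- c(bp, nchar(sequence))
    out <- seqs[rep(i, length(lo)), , drop = FALSE]
    out$id <- paste0(id, "_part", seq_along(lo))
    out$sequence <- substring(sequence, lo + 1L, hi)
    out
  })
  bind_rows(pieces)
}

#' Chimera percentage of an assembly
#'
#' @param n_chimeric number of chimeric contigs.
#' @param n_nonredundant nonredundant contig count (the denominator used for
#'   assembly comparison tables).
#' @return percentage, rounded half-up to 2 decimals.
#' @export
chimera_rate <- function(n_chimeric, n_nonredundant) {
  stopifnot(n_nonredundant > 0, n_chimeric >= 0,
            n_chimeric <= n_nonredundant)
  round_half_up(100 * n_chimeric / n_nonredundant, 2)
}
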