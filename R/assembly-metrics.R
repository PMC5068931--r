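# Contig-level statistics: length filtering, N50, redundancy removal at 100%
# identity (including exact containment on either strand), merged assemblies.

#' Drop contigs shorter than a minimum length
#'
#' @param seqs sequence tibble (`id`, `sequence`, ...).
#' @param min_len minimum retained length in bases (inclusive); assemblies in
#'   this package default to 200 downstream.
#' @return the filtered tibble, order preserved.
#' @export
filter_min_length <- function(seqs, min_len = 200) {
  stopifnot(min_len >= 1)
  filter(seqs, nchar(.data$sequence) >= min_len)
}

#' N50 of a set of contig lengths
#'
#' The smallest length L such that contigs of length >= L together contain at
#' least half of all assembled bases (computed by sorting descending and
#' accumulating).
#'
#' @param lengths positive contig lengths.
#' @return the N50, in bases.
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0) stop("n50 of an empty length set is undefined")
  stopifnot(all(lengths > 0))
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

#' Remove redundant contigs (100% identity, both strands)
#'
#' A contig is redundant when its sequence is identical to, or an exact
#' substring of, another contig on either strand. Within a redundancy
#' cluster the longest sequence is kept (ties broken by lexicographically
#' smallest id). This is the "nonredundant" notion behind CD-HIT-style
#' clustering at `-c 1.0`.
#'
#' @param seqs nucleotide sequence tibble.
#' @return the retained tibble (input order preserved) with a `removed`
#'   attribute: a tibble of (`id`, `kept_id`, `reason`), reason one of
#'   `identical`, `contained`, `contained_rc`. See [dedup_removed()].
#' @export
deduplicate <- function(seqs) {
  stopifnot(is.data.frame(seqs), all(c("id", "sequence") %in% names(seqs)))
  n <- nrow(seqs)
  empty_removed <- tibble(id = character(), kept_id = character(),
                          reason = character())
  if (n == 0) {
    attr(seqs, "removed") <- empty_removed
    return(seqs)
  }
  sq <- seqs$sequence
  rc <- revcomp(sq)
  canon <- pmin(sq, rc)

  # Stage 1: exact duplicates (either strand) via canonical-form grouping.
  # All members of a group share one length; keep the lexicographically
  # smallest id.
  ord <- order(canon, seqs$id)
  first_of_group <- !duplicated(canon[ord])
  keeper_idx <- ord[first_of_group]
  group_keeper <- keeper_idx[match(canon, canon[keeper_idx])]
  identical_removed <- which(seq_len(n) != group_keeper)
  removed <- tibble(
    id = seqs$id[identical_removed],
    kept_id = seqs$id[group_keeper[identical_removed]],
    reason = rep("identical", length(identical_removed))
  )

  # Stage 2: containment among the unique representatives. Scan in
  # decreasing length order against the concatenation of already-kept
  # sequences ('#'-separated so matches cannot cross a boundary).
  uniq <- sort(keeper_idx)
  uniq <- uniq[order(-nchar(sq[uniq]), seqs$id[uniq])]
  kept <- integer(0)
  offsets <- numeric(0)   # cumulative end position of each kept piece in hay
  hay <- ""
  for (i in uniq) {
    hit <- NA_integer_
    reason <- "contained"
    if (nzchar(hay)) {
      hit <- stringr::str_locate(hay, stringr::fixed(sq[i]))[1, 1]
      if (is.na(hit)) {
        hit <- stringr::str_locate(hay, stringr::fixed(rc[i]))[1, 1]
        reason <- "contained_rc"
      }
    }
    if (!is.na(hit)) {
      k <- findInterval(hit - 1, offsets) + 1L
      removed <- bind_rows(removed, tibble(
        id = seqs$id[i], kept_id = seqs$id[kept[k]], reason = reason))
      # redirect exact duplicates of i to the container as well
      dup_of_i <- removed$kept_id == seqs$id[i] & removed$reason == "identical"
      removed$kept_id[dup_of_i] <- seqs$id[kept[k]]
    } else {
      kept <- c(kept, i)
      hay <- paste0(hay, sq[i], "#")
      offsets <- c(offsets, nchar(hay))
    }
  }
  out <- seqs[sort(kept), , drop = FALSE]
  attr(out, "removed") <- removed[order(match(removed$id, seqs$id)), ]
  out
}

#' Removed-contig record of a deduplicated set
#'
#' @param seqs a tibble returned by [deduplicate()].
#' @return tibble of (`id`, `kept_id`, `reason`).
#' @export
dedup_removed <- function(seqs) {
  attr(seqs, "removed") %||%
    stop("no dedup record: was this produced by deduplicate()?")
}

#' Contig length statistics for one assembly
#'
#' The length half of an assembly comparison table: contig count,
#' nonredundant count, total and mean length, N50.
#'
#' @param seqs non-empty sequence tibble.
#' @param dedup compute the nonredundant count via [deduplicate()] (default);
#'   set `FALSE` to skip (nonredundant count reported as `NA`).
#' @return one-row tibble: `total_contigs`, `nonredundant_contigs`,
#'   `total_bases`, `mean_length` (rounded to integer bases), `n50`.
#' @export
length_stats <- function(seqs, dedup = TRUE) {
  if (nrow(seqs) == 0) stop("length_stats of an empty assembly is undefined")
  len <- nchar(seqs$sequence)
  tibble(
    total_contigs = nrow(seqs),
    nonredundant_contigs = if (dedup) nrow(deduplicate(seqs)) else NA_integer_,
    total_bases = sum(len),
    mean_length = round_half_up(mean(len)),
    n50 = n50(len)
  )
}

#' Merge assemblies into one labelled, deduplicated set
#'
#' Ids are prefixed `"<label>|"` so provenance stays recoverable, then the
#' union is deduplicated at 100% identity.
#'
#' @param sets list of sequence tibbles.
#' @param labels unique labels, one per set.
#' @return merged, deduplicated sequence tibble (with the [deduplicate()]
#'   `removed` attribute).
#' @export
merge_assemblies <- function(sets, labels) {
  stopifnot(length(sets) == length(labels), !anyDuplicated(labels))
  all <- bind_rows(purrr::map2(sets, labels, function(s, l) {
    mutate(s, id = paste0(l, "|", .data$id))
  }))
  deduplicate(all)
}
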