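# Reference-based assembly quality: per-reference coverage by interval
# unions, threshold-based completeness and contiguity, Ortholog Hit Ratio.
# Coverage is always measured on the subject (reference) axis; overlapping
# HSPs are union-merged, never summed.

maybe_normalize <- function(hits, ref_lengths = NULL) {
  if (!all(c("q_lo", "s_lo") %in% names(hits))) {
    hits <- normalize_hits(hits, ref_lengths)
  } else if (!is.null(ref_lengths)) {
    rl <- as_ref_lengths(ref_lengths)
    unknown <- setdiff(hits$subject_id, names(rl))
    if (length(unknown)) {
      stop("subject(s) missing from ref_lengths: ",
           paste(head(unknown, 5), collapse = ", "))
    }
    if (any(hits$s_hi > rl[hits$subject_id])) stop("hit beyond subject length")
  }
  hits
}

union_by_group <- function(lo, hi, group) {
  ir <- IRanges::IRanges(start = lo + 1L, end = hi)
  irl <- IRanges::reduce(S4Vectors::split(ir, factor(group, levels = unique(group))))
  setNames(sum(IRanges::width(irl)), unique(group))
}

#' Per-reference coverage summary
#'
#' For every reference, the fraction of its length covered by the union of
#' all hit intervals (`covered_all`) and by the single best-covering contig
#' (`covered_best_single`, with `best_contig_id`). References without hits
#' get zero coverage and an `NA` best contig.
#'
#' @param hits hit tibble ([read_hits_table()] output; normalized
#'   automatically).
#' @param ref_lengths named vector or two-column tibble of reference lengths
#'   (subject units: bases for nucleotide, residues for protein references).
#' @return tibble with columns `ref_id`, `ref_length`, `covered_all`,
#'   `covered_best_single`, `best_contig_id`.
#' @export
coverage_summary <- function(hits, ref_lengths) {
  rl <- as_ref_lengths(ref_lengths)
  hits <- maybe_normalize(hits, rl)
  out <- tibble(ref_id = names(rl), ref_length = unname(rl),
                covered_all = 0, covered_best_single = 0,
                best_contig_id = NA_character_)
  if (nrow(hits) > 0) {
    cov_all <- union_by_group(hits$s_lo, hits$s_hi, hits$subject_id)
    i <- match(names(cov_all), out$ref_id)
    out$covered_all[i] <- pmin(1, unname(cov_all) / out$ref_length[i])

    pair_key <- paste(hits$subject_id, hits$query_id, sep = "\r")
    cov_pair <- union_by_group(hits$s_lo, hits$s_hi, pair_key)
    pairs <- tibble(
      ref_id = sub("\r.*$", "", names(cov_pair)),
      contig_id = sub("^.*\r", "", names(cov_pair)),
      covered = unname(cov_pair)
    )
    best <- pairs |>
      arrange(.data$ref_id, dplyr::desc(.data$covered), .data$contig_id) |>
      distinct(.data$ref_id, .keep_all = TRUE)
    j <- match(best$ref_id, out$ref_id)
    out$covered_best_single[j] <- pmin(1, best$covered / out$ref_length[j])
    out$best_contig_id[j] <- best$contig_id
  }
  out
}

check_expressed <- function(cov, expressed) {
  if (is.null(expressed)) expressed <- cov$ref_id[cov$covered_all > 0]
  expressed <- unique(as.character(expressed))
  if (length(expressed) == 0) stop("the expressed reference set is empty")
  unknown <- setdiff(expressed, cov$ref_id)
  if (length(unknown)) {
    stop("expressed id(s) absent from the coverage summary: ",
         paste(head(unknown, 5), collapse = ", "))
  }
  expressed
}

#' Assembly completeness at a coverage threshold
#'
#' Percentage of expressed reference transcripts whose union coverage by all
#' contigs is at least `threshold` (inclusive).
#'
#' @param cov a [coverage_summary()] tibble.
#' @param expressed character vector of expressed reference ids; defaults to
#'   every reference with at least one hit.
#' @param threshold coverage fraction in (0, 1]; default 0.8.
#' @return percentage in `[0, 100]`.
#' @export
completeness <- function(cov, expressed = NULL, threshold = 0.8) {
  stopifnot(threshold > 0, threshold <= 1)
  expressed <- check_expressed(cov, expressed)
  sub <- cov[cov$ref_id %in% expressed, ]
  100 * mean(sub$covered_all >= threshold)
}

#' Assembly contiguity at a coverage threshold
#'
#' Percentage of expressed reference transcripts covered at least `threshold`
#' by a single best contig. Always `<=` [completeness()] at the same
#' threshold.
#'
#' @inheritParams completeness
#' @return percentage in `[0, 100]`.
#' @export
contiguity <- function(cov, expressed = NULL, threshold = 0.8) {
  stopifnot(threshold > 0, threshold <= 1)
  expressed <- check_expressed(cov, expressed)
  sub <- cov[cov$ref_id %in% expressed, ]
  100 * mean(sub$covered_best_single >= threshold)
}

#' Completeness/contiguity as functions of the coverage threshold
#'
#' @inheritParams completeness
#' @param thresholds ascending coverage fractions in (0, 1].
#' @return tibble (`threshold`, `completeness`, `contiguity`); both metric
#'   columns are non-increasing along the curve.
#' @export
metric_curve <- function(cov, expressed = NULL,
                         thresholds = seq(0.5, 1, by = 0.1)) {
  stopifnot(!is.unsorted(thresholds))
  expressed <- check_expressed(cov, expressed)
  tibble(
    threshold = thresholds,
    completeness = purrr::map_dbl(thresholds, ~completeness(cov, expressed, .x)),
    contiguity = purrr::map_dbl(thresholds, ~contiguity(cov, expressed, .x))
  )
}

#' Ortholog Hit Ratio per contig
#'
#' For each contig, its best reference subject is the one with the highest
#' summed bitscore across the contig-subject hit pair (ties: lowest evalue,
#' then lexicographically smallest subject id). The OHR is the fraction of
#' that subject's length covered by the union of the pair's subject
#' intervals, capped at 1.0; an OHR close to 1 means the transcript was
#' assembled to (at least) full reference length.
#'
#' @inheritParams coverage_summary
#' @return tibble (`contig_id`, `subject_id`, `ohr`), one row per contig with
#'   at least one hit.
#' @export
ortholog_hit_ratio <- function(hits, ref_lengths) {
  rl <- as_ref_lengths(ref_lengths)
  hits <- maybe_normalize(hits, rl)
  if (nrow(hits) == 0) {
    return(tibble(contig_id = character(), subject_id = character(),
                  ohr = double()))
  }
  pair_key <- paste(hits$query_id, hits$subject_id, sep = "\r")
  cov_pair <- union_by_group(hits$s_lo, hits$s_hi, pair_key)
  pairs <- hits |>
    group_by(.data$query_id, .data$subject_id) |>
    summarise(score = sum(.data$bitscore), evalue = min(.data$evalue),
              .groups = "drop") |>
    mutate(covered = unname(cov_pair[paste(.data$query_id, .data$subject_id,
                                           sep = "\r")]))
  pairs |>
    arrange(.data$query_id, dplyr::desc(.data$score), .data$evalue,
            .data$subject_id) |>
    distinct(.data$query_id, .keep_all = TRUE) |>
    mutate(ohr = pmin(1, .data$covered / unname(rl[.data$subject_id]))) |>
    select(contig_id = "query_id", subject_id = "subject_id", "ohr")
}
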