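# Orchestration: run length stats, redundancy removal, chimera scan and
# reference-based metrics over several assemblies and tabulate a
# comparison report, one row per assembly.

#' Evaluate and compare de novo assemblies
#'
#' Runs the full evaluation pipeline per assembly: minimum-length filter,
#' length statistics and N50, redundancy removal, chimera detection (with
#' the chimera percentage computed against the nonredundant count), and
#' completeness/contiguity at each threshold. The expressed reference set
#' (the denominator of completeness and contiguity) is computed once across
#' all assemblies — by default every reference hit by any assembly — so the
#' rows are comparable.
#'
#' @param assemblies named list; each element a list with `contigs` (a
#'   sequence tibble or FASTA path) and `hits` (a hit tibble or path to a
#'   12-column tabular file).
#' @param ref_lengths named vector or two-column tibble of reference
#'   lengths, or a reference FASTA path.
#' @param thresholds coverage thresholds for completeness/contiguity
#'   (default 0.8).
#' @param min_len minimum contig length retained (default 200).
#' @param expressed optional character vector of expressed reference ids.
#' @param chimera a [chimera_params()] list.
#' @return an object of class `evaluation_report`: list with `summary`
#'   (one row per assembly), `curves` (per-threshold metrics), `coverage`
#'   (per-assembly [coverage_summary()] tibbles), `expressed` and the
#'   parameters used. Has [tidy()] and [autoplot()] methods.
#' @export
evaluate_assemblies <- function(assemblies, ref_lengths,
                                thresholds = 0.8, min_len = 200,
                                expressed = NULL,
                                chimera = chimera_params()) {
  stopifnot(length(assemblies) >= 1, !is.null(names(assemblies)),
            !anyDuplicated(names(assemblies)))
  # fail fast on missing files before any computation starts
  for (label in names(assemblies)) {
    a <- assemblies[[label]]
    for (part in c("contigs", "hits")) {
      if (is.character(a[[part]]) && !file.exists(a[[part]])) {
        stop("assembly '", label, "': ", part, " file not found: ", a[[part]])
      }
    }
  }
  if (is.character(ref_lengths) && length(ref_lengths) == 1 &&
      is.null(names(ref_lengths))) {
    if (!file.exists(ref_lengths)) stop("reference FASTA not found: ", ref_lengths)
    rf <- read_fasta(ref_lengths)
    ref_lengths <- setNames(nchar(rf$sequence), rf$id)
  }
  rl <- as_ref_lengths(ref_lengths)

  loaded <- purrr::imap(assemblies, function(a, label) {
    contigs <- if (is.character(a$contigs)) read_fasta(a$contigs) else a$contigs
    hits <- if (is.character(a$hits)) read_hits_table(a$hits) else a$hits
    contigs <- filter_min_length(contigs, min_len)
    hits <- filter(hits, .data$query_id %in% contigs$id)
    list(contigs = contigs, hits = normalize_hits(hits, rl))
  })

  if (is.null(expressed)) {
    expressed <- sort(unique(unlist(
      purrr::map(loaded, ~unique(.x$hits$subject_id)))))
  }
  if (length(expressed) == 0) stop("the expressed reference set is empty")

  rows <- list(); curves <- list(); coverage <- list()
  for (label in names(loaded)) {
    x <- loaded[[label]]
    nonred <- deduplicate(x$contigs)
    stats <- length_stats(x$contigs, dedup = FALSE)
    stats$nonredundant_contigs <- nrow(nonred)
    calls <- detect_chimeras(
      filter(x$hits, .data$query_id %in% nonred$id), chimera)
    cov <- coverage_summary(x$hits, rl)
    coverage[[label]] <- cov
    mc <- metric_curve(cov, expressed, thresholds)
    curves[[label]] <- mutate(mc, label = label, .before = 1)
    rows[[label]] <- bind_cols(
      tibble(label = label), stats,
      tibble(
        chimeric_contigs = nrow(calls),
        chimera_pct = chimera_rate(nrow(calls), nrow(nonred))
      ),
      tidyr::pivot_wider(
        mc, names_from = "threshold",
        values_from = c("completeness", "contiguity"),
        names_glue = "{.value}_{threshold}")
    )
  }
  structure(
    list(summary = bind_rows(rows), curves = bind_rows(curves),
         coverage = coverage, expressed = expressed,
         params = list(thresholds = thresholds, min_len = min_len,
                       chimera = chimera)),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Assembly evaluation report (", nrow(x$summary), " assembl",
      if (nrow(x$summary) == 1) "y" else "ies", ", ",
      length(x$expressed), " expressed references)\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Percentage of items passing a filter
#'
#' Plain pass-rate arithmetic (e.g. read pairs surviving quality control),
#' rounded half-up.
#'
#' @param passed number of passing items.
#' @param total total items (> 0).
#' @param decimals decimal places (default 1).
#' @return percentage.
#' @export
pass_percentage <- function(passed, total, decimals = 1) {
  stopifnot(total > 0, passed >= 0, passed <= total)
  round_half_up(100 * passed / total, decimals)
}
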