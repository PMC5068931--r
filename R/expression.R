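# Expression quantification: FPKM from fragment counts, and
# efficiency-corrected relative qPCR expression (Pfaffl-style ratio
# E_ref^Cp_ref / E_target^Cp_target) with calibration-curve efficiency
# estimation, calibrator run correction and replicate aggregation.

#' Fit a qPCR calibration curve
#'
#' Ordinary least squares of Cp against log10(dilution) over a serial
#' dilution series. The amplification efficiency is `10^(-1/slope)`
#' (fold per cycle; 2 is perfect doubling). A non-negative slope is flagged
#' invalid; efficiencies above 2.2 draw a warning since chemistry cannot
#' exceed doubling by much.
#'
#' @param dilutions positive dilution factors (at least 3 distinct).
#' @param cps crossing-point values, same length.
#' @param gene_id optional gene label carried into the result.
#' @return an object of class `calibration_curve`: a list with `gene_id`,
#'   `slope` (Cp per log10 dilution), `intercept`, `efficiency`,
#'   `r_squared`, `n_points`, `valid` and the underlying `lm` fit. Has
#'   [tidy()], [glance()] and [autoplot()] methods.
#' @export
fit_calibration <- function(dilutions, cps, gene_id = NA_character_) {
  stopifnot(length(dilutions) == length(cps), all(dilutions > 0),
            all(cps > 0))
  if (length(unique(dilutions)) < 3) {
    stop("calibration requires at least 3 distinct dilutions")
  }
  d <- tibble(log_dil = log10(dilutions), cp = cps)
  fit <- lm(cp ~ log_dil, data = d)
  slope <- unname(coef(fit)[2])
  # summary.lm warns on an exactly collinear (noise-free) series; that is a
  # legitimate calibration here, not a modelling problem
  r2 <- suppressWarnings(summary(fit)$r.squared)
  valid <- is.finite(slope) && slope < 0
  efficiency <- if (valid) 10^(-1 / slope) else NA_real_
  if (valid && efficiency > 2.2) {
    warning("calibration efficiency ", signif(efficiency, 4),
            " exceeds 2.2 (more than doubling per cycle)")
  }
  structure(
    list(gene_id = gene_id, slope = slope,
         intercept = unname(coef(fit)[1]), efficiency = efficiency,
         r_squared = if (is.finite(r2)) r2 else NA_real_,
         n_points = length(cps), valid = valid, fit = fit, data = d),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("qPCR calibration curve",
      if (!is.na(x$gene_id)) paste0("for ", x$gene_id) else "", "\n")
  cat(sprintf("  slope %.4f Cp/log10(dilution), efficiency %s, R^2 %s, n = %d%s\n",
              x$slope,
              ifelse(x$valid, sprintf("%.4f", x$efficiency), "NA"),
              ifelse(is.na(x$r_squared), "NA", sprintf("%.4f", x$r_squared)),
              x$n_points,
              if (!x$valid) " [INVALID: non-negative slope]" else ""))
  invisible(x)
}

#' Fit calibration curves for every gene in a Cp table
#'
#' Uses the calibration-series rows (non-missing `dilution`), pooling
#' replicates per dilution point.
#'
#' @param cp_table a validated Cp tibble (see [read_cp_table()]).
#' @return named list of [fit_calibration()] objects, one per gene with
#'   calibration rows.
#' @export
fit_calibrations <- function(cp_table) {
  cp_table <- validate_cp_table(cp_table)
  cal <- filter(cp_table, !is.na(.data$dilution))
  if (nrow(cal) == 0) stop("Cp table contains no calibration-series rows")
  genes <- unique(cal$gene_id)
  setNames(
    purrr::map(genes, function(g) {
      rows <- filter(cal, .data$gene_id == g)
      fit_calibration(rows$dilution, rows$cp, gene_id = g)
    }),
    genes
  )
}

#' Efficiency-corrected relative expression ratio
#'
#' The ratio `E_ref^Cp_ref / E_target^Cp_target`, computed in log space.
#' With both efficiencies equal to 2 this reduces to
#' `2^(Cp_ref - Cp_target)`.
#'
#' @param e_ref,e_target amplification efficiencies in (1, 4].
#' @param cp_ref,cp_target positive crossing points.
#' @return the dimensionless ratio (vectorized).
#' @export
relative_ratio <- function(e_ref, cp_ref, e_target, cp_target) {
  stopifnot(all(e_ref > 1), all(e_ref <= 4), all(e_target > 1),
            all(e_target <= 4), all(cp_ref > 0), all(cp_target > 0))
  out <- exp(cp_ref * log(e_ref) - cp_target * log(e_target))
  if (any(!is.finite(out))) stop("non-finite expression ratio")
  out
}

#' Correct a ratio for run-to-run variation with a calibrator
#'
#' The calibrator is a sample measured in every run; a multiplicative run
#' effect cancels when each run's ratios are rescaled by the calibrator's
#' reading in a chosen reference run.
#'
#' @param sample_ratio ratio(s) measured in this run.
#' @param calibrator_ratio_this_run calibrator ratio in the same run.
#' @param calibrator_ratio_reference_run calibrator ratio in the reference
#'   run.
#' @return corrected ratio(s).
#' @export
calibrator_normalize <- function(sample_ratio, calibrator_ratio_this_run,
                                 calibrator_ratio_reference_run) {
  stopifnot(all(sample_ratio > 0), all(calibrator_ratio_this_run > 0),
            all(calibrator_ratio_reference_run > 0))
  sample_ratio * calibrator_ratio_reference_run / calibrator_ratio_this_run
}

#' Aggregate a Cp table into per-sample expression ratios
#'
#' Technical replicates are averaged on the Cp scale within each RT
#' replicate; one efficiency-corrected ratio is formed per RT replicate
#' against the reference gene's Cp from the same (sample, run, RT)
#' triple, so cDNA-load variation cancels within the physical specimen;
#' ratios are calibrator-corrected per run when calibrator rows are
#' present; the mean and sd across RT replicates are reported.
#'
#' @param cp_table validated Cp tibble (measurement rows have `dilution`
#'   `NA`; calibration rows are ignored here).
#' @param curves named list of [fit_calibration()] objects (or a tibble
#'   with `gene_id`, `efficiency`) covering every measured gene.
#' @param reference_gene id of the normalization gene (e.g. actin).
#' @param reference_run run id used as the calibrator baseline; default the
#'   first run in sorted order.
#' @return tibble of expression ratios: `sample_id`, `gene_id`, `ratio`,
#'   `sd`, `n_rt_replicates`, `normalization` (`"actin"`-style
#'   reference-gene normalization).
#' @export
aggregate_sample <- function(cp_table, curves, reference_gene,
                             reference_run = NULL) {
  cp_table <- validate_cp_table(cp_table)
  eff <- curve_efficiencies(curves)
  meas <- filter(cp_table, is.na(.data$dilution))
  genes <- unique(meas$gene_id)
  if (!reference_gene %in% genes) {
    stop("reference gene '", reference_gene, "' has no measurements")
  }
  missing_eff <- setdiff(genes, names(eff))
  if (length(missing_eff)) {
    stop("no calibration curve for gene(s): ",
         paste(missing_eff, collapse = ", "))
  }

  by_rt <- meas |>
    group_by(.data$sample_id, .data$gene_id, .data$run_id,
             .data$rt_replicate, .data$role) |>
    summarise(cp = mean(.data$cp), .groups = "drop")

  ref_cp <- by_rt |>
    filter(.data$gene_id == reference_gene) |>
    select("sample_id", "run_id", "rt_replicate", ref_cp = "cp")
  targets <- by_rt |>
    filter(.data$gene_id != reference_gene) |>
    left_join(ref_cp, by = c("sample_id", "run_id", "rt_replicate"))
  if (any(is.na(targets$ref_cp))) {
    bad <- distinct(targets[is.na(targets$ref_cp), ],
                    .data$sample_id, .data$run_id, .data$rt_replicate)
    stop("missing reference-gene Cp for run(s): ",
         paste(unique(paste0(bad$sample_id, "/", bad$run_id,
                             "/rt", bad$rt_replicate)), collapse = ", "))
  }
  targets <- mutate(targets,
    ratio = relative_ratio(eff[reference_gene], .data$ref_cp,
                           eff[.data$gene_id], .data$cp))

  cal <- filter(targets, .data$role == "calibrator")
  if (nrow(cal) > 0) {
    runs <- sort(unique(targets$run_id))
    reference_run <- reference_run %||% runs[1]
    cal_run <- cal |>
      group_by(.data$gene_id, .data$run_id) |>
      summarise(cal_ratio = exp(mean(log(.data$ratio))), .groups = "drop")
    base <- cal_run |>
      filter(.data$run_id == reference_run) |>
      select("gene_id", cal_ref = "cal_ratio")
    if (nrow(base) == 0) {
      stop("calibrator not measured in reference run '", reference_run, "'")
    }
    targets <- targets |>
      left_join(cal_run, by = c("gene_id", "run_id")) |>
      left_join(base, by = "gene_id") |>
      mutate(ratio = calibrator_normalize(.data$ratio, .data$cal_ratio,
                                          .data$cal_ref)) |>
      select(-"cal_ratio", -"cal_ref")
  }

  targets |>
    filter(.data$role != "calibrator") |>
    group_by(.data$sample_id, .data$gene_id) |>
    summarise(mean_ratio = mean(.data$ratio),
              sd = if (n() > 1) sd(.data$ratio) else 0,
              n_rt_replicates = n(), .groups = "drop") |>
    rename(ratio = "mean_ratio") |>
    mutate(normalization = "actin")
}

curve_efficiencies <- function(curves) {
  if (is.data.frame(curves)) {
    return(setNames(curves$efficiency, curves$gene_id))
  }
  if (inherits(curves, "calibration_curve")) curves <- list(curves)
  eff <- purrr::map_dbl(curves, function(cv) {
    if (!cv$valid) stop("invalid calibration curve for gene ", cv$gene_id)
    cv$efficiency
  })
  nm <- names(curves) %||% purrr::map_chr(curves, "gene_id")
  if (is.null(names(curves))) names(eff) <- nm
  eff
}

#' Rescale cDNA-normalized ratios into reference-gene-normalized space
#'
#' When the reference gene cannot be used (e.g. RNA from seeds where actin
#' expression is too low), ratios normalized by cDNA amount are bridged
#' into the reference-gene-normalized scale via samples measured under both
#' normalizations: the scale factor is the geometric mean of
#' `actin_value / cdna_value` over the bridge samples.
#'
#' @param ratios tibble of expression ratios (with a `ratio` column), or a
#'   numeric vector.
#' @param bridge tibble (or data frame) with columns `cdna_value` and
#'   `actin_value`, one row per bridge sample; all values positive.
#' @return rescaled ratios; for a tibble input, `normalization` is set to
#'   `"cdna_rescaled"`.
#' @export
cdna_rescale <- function(ratios, bridge) {
  stopifnot(is.data.frame(bridge),
            all(c("cdna_value", "actin_value") %in% names(bridge)))
  if (nrow(bridge) == 0) stop("at least one bridge sample is required")
  stopifnot(all(bridge$cdna_value > 0), all(bridge$actin_value > 0))
  scale <- exp(mean(log(bridge$actin_value / bridge$cdna_value)))
  if (is.data.frame(ratios)) {
    mutate(ratios, ratio = .data$ratio * scale,
           normalization = "cdna_rescaled")
  } else {
    stopifnot(all(ratios > 0))
    ratios * scale
  }
}

#' Fragments per kilobase of transcript per million mapped fragments
#'
#' @param fragments fragment count(s) assigned to the transcript.
#' @param transcript_length transcript length(s) in bases.
#' @param total_mapped_fragments library size (total mapped fragments).
#' @return FPKM value(s):
#'   `fragments / ((transcript_length/1e3) * (total_mapped_fragments/1e6))`.
#' @export
fpkm <- function(fragments, transcript_length, total_mapped_fragments) {
  stopifnot(all(fragments >= 0))
  if (any(transcript_length <= 0)) stop("transcript_length must be positive")
  if (any(total_mapped_fragments <= 0)) stop("library size must be positive")
  fragments / ((transcript_length / 1e3) * (total_mapped_fragments / 1e6))
}
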