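# broom-style tidiers for the package's fitted/result objects.

#' Tidy a qPCR calibration curve
#'
#' @param x a [fit_calibration()] object.
#' @param ... unused.
#' @return one-row tibble with `gene_id`, `slope`, `intercept`,
#'   `efficiency`, `r_squared`, `n_points`, `valid`.
#' @method tidy calibration_curve
#' @export
tidy.calibration_curve <- function(x, ...) {
  tibble(gene_id = x$gene_id, slope = x$slope, intercept = x$intercept,
         efficiency = x$efficiency, r_squared = x$r_squared,
         n_points = x$n_points, valid = x$valid)
}

#' @rdname tidy.calibration_curve
#' @method glance calibration_curve
#' @export
glance.calibration_curve <- function(x, ...) tidy(x)

#' Tidy a pairwise Ka/Ks result
#'
#' @param x a [kaks()] object.
#' @param ... unused.
#' @return one-row tibble with the site counts, differences, proportions,
#'   corrected distances and the Ka/Ks ratio.
#' @method tidy kaks_result
#' @export
tidy.kaks_result <- function(x, ...) {
  tibble(n_codons_used = x$n_codons_used, S = x$S, N = x$N,
         Sd = x$Sd, Nd = x$Nd, pS = x$pS, pN = x$pN,
         Ks = x$Ks, Ka = x$Ka, ratio = x$ratio)
}

#' @rdname tidy.kaks_result
#' @method glance kaks_result
#' @export
glance.kaks_result <- function(x, ...) {
  tibble(Ka = x$Ka, Ks = x$Ks, ratio = x$ratio,
         n_codons_used = x$n_codons_used)
}

#' Tidy an assembly evaluation report
#'
#' @param x an [evaluate_assemblies()] report.
#' @param ... unused.
#' @return the per-assembly summary tibble.
#' @method tidy evaluation_report
#' @export
tidy.evaluation_report <- function(x, ...) x$summary

#' @rdname tidy.evaluation_report
#' @method glance evaluation_report
#' @export
glance.evaluation_report <- function(x, ...) {
  tibble(n_assemblies = nrow(x$summary),
         n_expressed_refs = length(x$expressed),
         thresholds = paste(x$params$thresholds, collapse = ","))
}
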