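# qPCR crossing-point (Cp) tables.

CP_COLS <- c("sample_id", "gene_id", "run_id", "rt_replicate",
             "tech_replicate", "cp", "role", "dilution")
CP_ROLES <- c("target", "reference", "calibrator")

#' Read a qPCR Cp table from CSV
#'
#' Expected columns: `sample_id`, `gene_id`, `run_id`, `rt_replicate`,
#' `tech_replicate`, `cp`, `role` (target / reference / calibrator) and
#' optionally `dilution` (positive factor; non-`NA` only on
#' calibration-series rows). Comma separator, `.` decimal, UTF-8.
#'
#' @param path path to the CSV file.
#' @return a validated Cp tibble.
#' @export
read_cp_table <- function(path) {
  if (!file.exists(path)) stop("Cp table not found: ", path)
  cp <- readr::read_csv(path, show_col_types = FALSE)
  if (!"dilution" %in% names(cp)) cp$dilution <- NA_real_
  validate_cp_table(cp)
}

#' Validate a Cp table
#'
#' Checks column presence, finite positive Cp values, known roles, positive
#' dilutions, and uniqueness of the
#' (sample, gene, run, rt, tech, dilution) key.
#'
#' @param cp a Cp tibble.
#' @return the tibble, with columns coerced to canonical types.
#' @export
validate_cp_table <- function(cp) {
  missing <- setdiff(setdiff(CP_COLS, "dilution"), names(cp))
  if (length(missing)) {
    stop("Cp table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (!"dilution" %in% names(cp)) cp$dilution <- NA_real_
  cp <- mutate(as_tibble(cp),
    sample_id = as.character(.data$sample_id),
    gene_id = as.character(.data$gene_id),
    run_id = as.character(.data$run_id),
    rt_replicate = as.integer(.data$rt_replicate),
    tech_replicate = as.integer(.data$tech_replicate),
    cp = as.numeric(.data$cp),
    role = as.character(.data$role),
    dilution = as.numeric(.data$dilution)
  )
  if (any(!is.finite(cp$cp)) || any(cp$cp <= 0)) {
    stop("cp values must be finite and positive")
  }
  if (!all(cp$role %in% CP_ROLES)) {
    stop("unknown role(s): ",
         paste(setdiff(unique(cp$role), CP_ROLES), collapse = ", "))
  }
  if (any(!is.na(cp$dilution) & cp$dilution <= 0)) {
    stop("dilution factors must be positive")
  }
  key <- paste(cp$sample_id, cp$gene_id, cp$run_id, cp$rt_replicate,
               cp$tech_replicate, cp$dilution, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (sample, gene, run, rt, tech) measurement(s)")
  }
  cp[CP_COLS]
}

#' Write a Cp table to CSV
#'
#' @param cp a Cp tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cp_table <- function(cp, path) {
  readr::write_csv(validate_cp_table(cp), path)
  invisible(path)
}
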