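# Generators for qPCR Cp tables and divergent coding-sequence pairs.

#' Design (ground truth) for a simulated qPCR experiment
#'
#' @param efficiencies named vector of true amplification efficiencies in
#'   (1, 2.2], one entry per gene including the reference gene.
#' @param ratios tibble (`sample_id`, `gene_id`, `ratio`) of true relative
#'   expression (reference-gene-normalized); genes must be target genes.
#' @param reference_gene name of the normalization gene (default
#'   `"actin"`).
#' @param noise_sd Gaussian noise on Cp, in cycles (default 0.15).
#' @param run_offsets named vector of per-run additive Cp offsets; the
#'   first run is the baseline and is forced to offset 0 so that
#'   calibrator-corrected ratios are on the design scale.
#' @return a `qpcr_design` list used by [simulate_qpcr()].
#' @export
qpcr_design <- function(efficiencies, ratios, reference_gene = "actin",
                        noise_sd = 0.15, run_offsets = c(run1 = 0)) {
  stopifnot(all(efficiencies > 1), all(efficiencies <= 2.2),
            !is.null(names(efficiencies)),
            all(c("sample_id", "gene_id", "ratio") %in% names(ratios)),
            all(ratios$ratio > 0),
            reference_gene %in% names(efficiencies),
            all(ratios$gene_id %in% names(efficiencies)),
            !is.null(names(run_offsets)))
  run_offsets <- run_offsets - run_offsets[1]
  # per-gene base Cp at unit amount, chosen so E_g^base is one shared
  # constant (a perfect-doubling gene sits at Cp 25); with this convention
  # the Pfaffl ratio in the baseline run equals the designed ratio exactly
  base_cp <- log(2^25) / log(efficiencies)
  structure(list(efficiencies = efficiencies, ratios = as_tibble(ratios),
                 reference_gene = reference_gene, noise_sd = noise_sd,
                 run_offsets = run_offsets, base_cp = base_cp),
            class = "qpcr_design")
}

#' Simulate a Cp table from a qPCR design
#'
#' Cp values follow
#' `base_cp(gene) + run_offset - log_E(amount) + N(0, noise_sd)`, with the
#' reference gene at unit amount in every sample. A calibrator sample
#' (unit amounts) is measured in every run, and a 10-fold dilution series
#' of a pooled sample is emitted per gene (rows with non-`NA` `dilution`)
#' so calibration curves can be fitted from the same table.
#'
#' @param design a [qpcr_design()].
#' @param n_rt independent RT (reverse-transcription) replicates per
#'   sample (default 2).
#' @param n_tech technical qPCR replicates per RT replicate (default 2).
#' @param seed integer seed.
#' @param dilutions dilution series for the calibration rows (default
#'   `c(1, 0.1, 0.01)`).
#' @return a validated Cp tibble (see [read_cp_table()] for the layout).
#' @export
simulate_qpcr <- function(design, n_rt = 2, n_tech = 2, seed,
                          dilutions = c(1, 0.1, 0.01)) {
  stopifnot(inherits(design, "qpcr_design"), n_rt >= 1, n_tech >= 1)
  with_rng(seed, {
    eff <- design$efficiencies
    runs <- names(design$run_offsets)
    samples <- unique(design$ratios$sample_id)
    sample_run <- setNames(rep(runs, length.out = length(samples)), samples)

    amount_rows <- bind_rows(
      # target genes at designed amounts
      mutate(design$ratios, role = "target", run_id = sample_run[.data$sample_id]),
      # reference gene at unit amount in every sample
      tibble(sample_id = samples, gene_id = design$reference_gene,
             ratio = 1, role = "reference", run_id = sample_run[samples]),
      # calibrator sample at unit amounts, in every run
      tidyr::expand_grid(run_id = runs,
                         gene_id = unique(design$ratios$gene_id)) |>
        mutate(sample_id = "calibrator", ratio = 1, role = "calibrator"),
      tibble(run_id = runs, gene_id = design$reference_gene,
             sample_id = "calibrator", ratio = 1, role = "reference")
    )

    meas <- dplyr::cross_join(
      amount_rows,
      tidyr::expand_grid(rt_replicate = seq_len(n_rt),
                         tech_replicate = seq_len(n_tech))
    ) |>
      mutate(
        cp = design$base_cp[.data$gene_id] +
          design$run_offsets[.data$run_id] -
          log(.data$ratio) / log(eff[.data$gene_id]) +
          rnorm(n(), 0, design$noise_sd),
        dilution = NA_real_
      ) |>
      select("sample_id", "gene_id", "run_id", "rt_replicate",
             "tech_replicate", "cp", "role", "dilution")

    cal <- tidyr::expand_grid(
      gene_id = names(eff),
      dilution = dilutions,
      tech_replicate = seq_len(n_tech)
    ) |>
      mutate(
        sample_id = "dilution_series", run_id = runs[1], rt_replicate = 1L,
        role = ifelse(.data$gene_id == design$reference_gene,
                      "reference", "target"),
        cp = design$base_cp[.data$gene_id] -
          log(.data$dilution) / log(eff[.data$gene_id]) +
          rnorm(n(), 0, design$noise_sd)
      ) |>
      select("sample_id", "gene_id", "run_id", "rt_replicate",
             "tech_replicate", "cp", "role", "dilution")

    validate_cp_table(bind_rows(meas, cal))
  })
}

#' Simulate an aligned coding-sequence pair with known divergence
#'
#' Builds a random stop-free CDS, then plants at most one single-base
#' change per codon, classified as synonymous or nonsynonymous at planting
#' time, until the target proportions `pS = Sd/S` and `pN = Nd/N` (sites
#' counted on the ancestral sequence) are met as closely as whole changes
#' allow. Changes creating stop codons are never planted.
#'
#' @param n_codons number of codons.
#' @param target_pN,target_pS target proportions, each in [0, 0.75).
#' @param seed integer seed.
#' @return list with `seq_a`, `seq_b` and `truth` (`Sd`, `Nd` planted
#'   counts, `S`, `N` ancestral site counts, `n_codons`).
#' @export
simulate_divergent_pair <- function(n_codons, target_pN, target_pS, seed) {
  stopifnot(n_codons >= 1, target_pN >= 0, target_pN < 0.75,
            target_pS >= 0, target_pS < 0.75)
  with_rng(seed, {
    gc <- genetic_code()
    sense <- names(gc)[gc != "*"]
    cods <- sample(sense, n_codons, replace = TRUE)
    tab <- site_table("nonsyn")
    S <- sum(tab[cods, "s"]); N <- sum(tab[cods, "n"])
    n_s <- round(target_pS * S); n_n <- round(target_pN * N)
    if (n_s + n_n > n_codons) {
      stop("targets need ", n_s + n_n, " changed codons but only ",
           n_codons, " are available")
    }
    # per codon, the possible single-base mutants split by class
    mutants <- function(codon, class) {
      p <- strsplit(codon, "")[[1]]
      out <- character(0)
      for (pos in 1:3) for (b in setdiff(NT, p[pos])) {
        q <- p; q[pos] <- b
        m <- paste(q, collapse = "")
        if (gc[m] == "*") next
        if (class == "syn" && gc[m] == gc[codon]) out <- c(out, m)
        if (class == "nonsyn" && gc[m] != gc[codon]) out <- c(out, m)
      }
      out
    }
    cods_b <- cods
    free <- sample(seq_len(n_codons))  # random planting order
    planted_s <- 0; planted_n <- 0
    for (i in free) {
      if (planted_s >= n_s && planted_n >= n_n) break
      if (planted_s < n_s) {
        ms <- mutants(cods[i], "syn")
        if (length(ms)) {
          cods_b[i] <- ms[sample.int(length(ms), 1)]
          planted_s <- planted_s + 1
          next
        }
      }
      if (planted_n < n_n) {
        mn <- mutants(cods[i], "nonsyn")
        if (length(mn)) {
          cods_b[i] <- mn[sample.int(length(mn), 1)]
          planted_n <- planted_n + 1
        }
      }
    }
    if (planted_s < n_s || planted_n < n_n) {
      stop("could not plant the requested number of changes")
    }
    list(seq_a = paste(cods, collapse = ""),
         seq_b = paste(cods_b, collapse = ""),
         truth = list(Sd = planted_s, Nd = planted_n, S = S, N = N,
                      n_codons = n_codons))
  })
}
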