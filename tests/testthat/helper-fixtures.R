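# Shared fixture builders.

# One hit row in the 12-column tabular layout.
mk_hit <- function(q, s, qs, qe, ss, se, bits = 100, ev = 1e-30, id = 100) {
  tibble::tibble(query_id = q, subject_id = s, pct_identity = id,
                 aln_length = abs(qe - qs) + 1L, mismatches = 0L,
                 gap_opens = 0L, q_start = qs, q_end = qe, s_start = ss,
                 s_end = se, evalue = ev, bitscore = bits)
}

# Small qPCR design with two target genes and distinct efficiencies.
demo_qpcr_design <- function(noise_sd = 0,
                             run_offsets = c(run1 = 0, run2 = 0.8)) {
  qpcr_design(
    efficiencies = c(actin = 1.95, ft1 = 1.90, tfl1 = 2.00),
    ratios = tibble::tibble(
      sample_id = rep(c("leaf", "root"), each = 2),
      gene_id = rep(c("ft1", "tfl1"), 2),
      ratio = c(5, 0.5, 1, 2)),
    reference_gene = "actin",
    noise_sd = noise_sd,
    run_offsets = run_offsets)
}
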