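# Synthetic-data generators with attached ground truth. Every generator is
# a pure function of (parameters, seed): reruns are byte-identical. Hit
# tables are idealized by default (identity 100, every interval an exact
# image of its source substring); an optional noise model adds identity
# jitter, interval trimming and sub-threshold decoy hits.

#' Simulate a reference transcript set
#'
#' Uniform-random nucleotide sequences standing in for a set of reference
#' transcripts (orthologs) that contigs are evaluated against.
#'
#' @param n_refs number of references (>= 1).
#' @param length_range integer range (min, max) of reference lengths.
#' @param seed integer seed; same seed, same output.
#' @return sequence tibble (`id`, `sequence`, `description`).
#' @export
simulate_reference <- function(n_refs, length_range = c(600, 2000), seed) {
  stopifnot(n_refs >= 1, length(length_range) == 2,
            length_range[1] >= 1, length_range[1] <= length_range[2])
  with_rng(seed, {
    lens <- length_range[1] +
      sample.int(length_range[2] - length_range[1] + 1L, n_refs,
                 replace = TRUE) - 1L
    tibble(
      id = sprintf("ref%04d", seq_len(n_refs)),
      sequence = vapply(lens, function(L) {
        paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
      }, character(1)),
      description = ""
    )
  })
}

# 0-based half-open interval-union length by sort-and-merge; kept free of
# IRanges on purpose (this is the truth-side arithmetic).
union_len_naive <- function(lo, hi) {
  if (length(lo) == 0) return(0)
  o <- order(lo, hi)
  lo <- lo[o]; hi <- hi[o]
  total <- 0
  cur_lo <- lo[1]; cur_hi <- hi[1]
  for (k in seq_along(lo)[-1]) {
    if (lo[k] > cur_hi) {
      total <- total + (cur_hi - cur_lo)
      cur_lo <- lo[k]; cur_hi <- hi[k]
    } else {
      cur_hi <- max(cur_hi, hi[k])
    }
  }
  total + (cur_hi - cur_lo)
}

hit_row <- function(query_id, subject_id, q_lo, q_hi, s_lo, s_hi,
                    strand = "+") {
  len <- q_hi - q_lo
  tibble(
    query_id = query_id, subject_id = subject_id,
    pct_identity = 100, aln_length = as.integer(len),
    mismatches = 0L, gap_opens = 0L,
    q_start = as.integer(q_lo + 1), q_end = as.integer(q_hi),
    s_start = as.integer(if (strand == "+") s_lo + 1 else s_hi),
    s_end = as.integer(if (strand == "+") s_hi else s_lo + 1),
    evalue = 1e-180, bitscore = 2 * len
  )
}

#' Simulate a de novo assembly of a reference set, with ground truth
#'
#' Contigs are drawn as reference substrings: per reference, one "best"
#' fragment sized by the designed single-contig coverage, plus disjoint
#' filler fragments up to the designed union coverage. A `dup_rate`
#' fraction of fragments is re-emitted as exact duplicates, contained
#' copies, or reverse-complemented contained copies; chimeric contigs are
#' planted at `chimera_rate` (of the final contig count) by joining parts
#' of two references (trans) or tandem-repeating one part (self), the
#' parts preferentially drawn from uncovered reference regions so that
#' coverage truth is unaffected. The emitted hit table maps every contig
#' piece exactly to its source interval.
#'
#' @param reference a [simulate_reference()] tibble.
#' @param frag_mean,frag_sd filler-fragment length distribution (bases).
#' @param dup_rate fraction of fragments re-emitted redundantly, in [0, 1].
#' @param chimera_rate target fraction of chimeric contigs among all
#'   nonredundant contigs, in [0, 0.5].
#' @param coverage_design optional tibble (`ref_id`, `covered_all`,
#'   `covered_best_single`); by default drawn per reference as
#'   `covered_all ~ U(0.65, 0.98)` with best-single a `U(0.35, 1)` share.
#' @param seed integer seed.
#' @param noise `NULL` (idealized hits) or a list with any of
#'   `identity_jitter` (sd of downward identity jitter, default 5),
#'   `trim_max` (max bases trimmed per hit end, default 20), `decoy_rate`
#'   (sub-threshold decoy hits per contig, default 0.05).
#' @return list with `contigs` (sequence tibble), `hits` (12-column hit
#'   tibble) and `truth`: `contigs` (per-contig provenance: role, source
#'   intervals, `dup_of`, chimera kind and true breakpoint), `references`
#'   (per-reference realized `covered_all` / `covered_best_single`), and
#'   realized `chimera_rate`.
#' @export
simulate_assembly <- function(reference, frag_mean = 400, frag_sd = 120,
                              dup_rate = 0, chimera_rate = 0,
                              coverage_design = NULL, seed, noise = NULL) {
  stopifnot(dup_rate >= 0, dup_rate <= 1, chimera_rate >= 0,
            chimera_rate <= 0.5)
  if (chimera_rate > 0 && nrow(reference) < 2) {
    stop("chimera planting requires at least 2 references")
  }
  with_rng(seed, {
    n_refs <- nrow(reference)
    ref_len <- setNames(nchar(reference$sequence), reference$id)
    design <- coverage_design %||% tibble(
      ref_id = reference$id,
      covered_all = runif(n_refs, 0.65, 0.98),
      covered_best_single = NA_real_
    )
    if (all(is.na(design$covered_best_single))) {
      design$covered_best_single <-
        pmax(design$covered_all * runif(nrow(design), 0.35, 1),
             30 / ref_len[design$ref_id])
    }
    stopifnot(all(design$covered_best_single <= design$covered_all + 1e-12),
              all(design$covered_all <= 1))

    frag_ref <- character(0)  # accumulators, one entry per fragment
    frag_lo <- list()
    frag_hi <- list()
    free_gaps <- list()
    for (i in seq_len(nrow(design))) {
      rid <- design$ref_id[i]
      L <- ref_len[[rid]]
      b <- max(25L, as.integer(round(design$covered_best_single[i] * L)))
      b <- min(b, L)
      c_total <- min(L, max(b, round(design$covered_all[i] * L)))
      u <- sample.int(L - b + 1L, 1) - 1L
      ints <- list(c(u, u + b))  # best fragment first
      a_rem <- c_total - b
      if (a_rem < 25) a_rem <- 0
      for (gap in list(c(0L, u), c(u + b, L))) {
        pos <- gap[1]
        while (a_rem >= 25 && gap[2] - pos >= 25) {
          want <- round(rnorm(1, frag_mean, frag_sd))
          want <- max(25, min(want, b, a_rem, gap[2] - pos))
          if (a_rem - want < 25 && a_rem <= min(b, gap[2] - pos)) {
            want <- a_rem
          }
          ints <- c(ints, list(c(pos, pos + want)))
          pos <- pos + want
          a_rem <- a_rem - want
        }
        if (gap[2] - pos >= 25) {
          free_gaps <- c(free_gaps, list(c(rid, pos, gap[2])))
        }
      }
      m <- do.call(rbind, ints)
      frag_ref <- c(frag_ref, rep(rid, nrow(m)))
      frag_lo <- c(frag_lo, list(m[, 1]))
      frag_hi <- c(frag_hi, list(m[, 2]))
    }

    frag <- tibble(ref_id = frag_ref,
                   lo = as.integer(unlist(frag_lo)),
                   hi = as.integer(unlist(frag_hi)))
    n_frag <- nrow(frag)
    frag$contig_id <- sprintf("ctg%05d", seq_len(n_frag))
    ref_seq <- setNames(reference$sequence, reference$id)
    frag$sequence <- substring(ref_seq[frag$ref_id], frag$lo + 1, frag$hi)

    contigs <- tibble(id = frag$contig_id, sequence = frag$sequence,
                      description = "")
    frag_len <- frag$hi - frag$lo
    hits <- list(tibble(
      query_id = frag$contig_id, subject_id = frag$ref_id,
      pct_identity = 100, aln_length = as.integer(frag_len),
      mismatches = 0L, gap_opens = 0L,
      q_start = 1L, q_end = as.integer(frag_len),
      s_start = frag$lo + 1L, s_end = frag$hi,
      evalue = 1e-180, bitscore = 2 * frag_len
    ))
    truth_contigs <- tibble(
      contig_id = frag$contig_id, role = "fragment",
      ref_id = frag$ref_id, src_lo = frag$lo, src_hi = frag$hi,
      dup_of = NA_character_, chim_kind = NA_character_,
      true_breakpoint = NA_integer_
    )
    intervals <- select(frag, "contig_id", "ref_id", "lo", "hi")

    # --- planted duplicates -------------------------------------------
    n_dup <- round(dup_rate * n_frag)
    if (n_dup > 0) {
      src <- sample.int(n_frag, n_dup, replace = FALSE)
      kinds <- sample(c("identical", "contained", "contained_rc"), n_dup,
                      replace = TRUE)
      acc <- vector("list", n_dup)
      for (k in seq_len(n_dup)) {
        fr <- frag[src[k], ]
        len <- fr$hi - fr$lo
        kind <- if (len < 45) "identical" else kinds[k]
        if (kind == "identical") {
          lo <- fr$lo; hi <- fr$hi
        } else {
          t1 <- sample(5:10, 1); t2 <- sample(5:10, 1)
          lo <- fr$lo + t1; hi <- fr$hi - t2
        }
        sq <- substring(ref_seq[[fr$ref_id]], lo + 1, hi)
        strand <- "+"
        if (kind == "contained_rc") {
          sq <- revcomp(sq)
          strand <- "-"
        }
        did <- sprintf("dup%04d", k)
        acc[[k]] <- list(id = did, sequence = sq, ref_id = fr$ref_id,
                         lo = lo, hi = hi, strand = strand,
                         dup_of = fr$contig_id)
      }
      dup <- bind_rows(purrr::map(acc, as_tibble))
      contigs <- bind_rows(contigs, tibble(id = dup$id,
                                           sequence = dup$sequence,
                                           description = ""))
      hits <- c(hits, purrr::pmap(dup, function(id, ref_id, lo, hi, strand,
                                                ...) {
        hit_row(id, ref_id, 0L, hi - lo, lo, hi, strand)
      }))
      truth_contigs <- bind_rows(truth_contigs, tibble(
        contig_id = dup$id, role = "duplicate", ref_id = dup$ref_id,
        src_lo = dup$lo, src_hi = dup$hi, dup_of = dup$dup_of,
        chim_kind = NA_character_, true_breakpoint = NA_integer_))
      intervals <- bind_rows(intervals, tibble(
        contig_id = dup$id, ref_id = dup$ref_id, lo = dup$lo, hi = dup$hi))
    }

    # --- planted chimeras ---------------------------------------------
    gap_tbl <- if (length(free_gaps)) {
      tibble(ref_id = purrr::map_chr(free_gaps, 1),
             lo = as.integer(purrr::map_chr(free_gaps, 2)),
             hi = as.integer(purrr::map_chr(free_gaps, 3)))
    } else {
      tibble(ref_id = character(), lo = integer(), hi = integer())
    }
    best_tbl <- frag |>
      group_by(.data$ref_id) |>
      slice(1) |>       # the best fragment was emitted first per reference
      ungroup()

    take_part <- function(len, avoid_ref = NULL) {
      # prefer an unused (free) region; fall back inside a best fragment
      cand <- which(gap_tbl$hi - gap_tbl$lo >= len &
                      !(gap_tbl$ref_id %in% avoid_ref))
      if (length(cand)) {
        g <- cand[sample.int(length(cand), 1)]
        lo <- gap_tbl$lo[g]
        gap_tbl$lo[g] <<- lo + len
        return(list(ref_id = gap_tbl$ref_id[g], lo = lo, hi = lo + len))
      }
      cand <- which(best_tbl$hi - best_tbl$lo >= len &
                      !(best_tbl$ref_id %in% avoid_ref))
      if (!length(cand)) return(NULL)
      g <- cand[sample.int(length(cand), 1)]
      lo <- best_tbl$lo[g]
      list(ref_id = best_tbl$ref_id[g], lo = lo, hi = lo + len)
    }

    # chimeras are counted against the nonredundant total (fragments plus
    # chimeras), so solve n_chim / (n_frag + n_chim) = chimera_rate
    n_chim <- round(chimera_rate / (1 - chimera_rate) * n_frag)
    if (n_chim > 0) {
      kinds <- sample(c("trans", "self"), n_chim, replace = TRUE)
      c_ctg <- vector("list", n_chim)
      c_hit <- vector("list", n_chim)
      c_tru <- vector("list", n_chim)
      c_int <- vector("list", n_chim)
      for (k in seq_len(n_chim)) {
        l1 <- sample(150:350, 1); l2 <- sample(150:350, 1)
        p1 <- take_part(l1)
        if (is.null(p1)) stop("no room left to place a chimera part")
        if (kinds[k] == "trans") {
          p2 <- take_part(l2, avoid_ref = p1$ref_id)
          if (is.null(p2)) stop("no second reference with room for a trans chimera")
        } else {
          p2 <- p1
        }
        s1 <- substring(ref_seq[[p1$ref_id]], p1$lo + 1, p1$hi)
        s2 <- substring(ref_seq[[p2$ref_id]], p2$lo + 1, p2$hi)
        cid <- sprintf("chi%04d", k)
        bp <- nchar(s1)
        c_ctg[[k]] <- tibble(id = cid, sequence = paste0(s1, s2),
                             description = "")
        c_hit[[k]] <- bind_rows(
          hit_row(cid, p1$ref_id, 0L, p1$hi - p1$lo, p1$lo, p1$hi),
          hit_row(cid, p2$ref_id, bp, bp + (p2$hi - p2$lo), p2$lo, p2$hi))
        c_tru[[k]] <- tibble(
          contig_id = cid, role = "chimera", ref_id = p1$ref_id,
          src_lo = p1$lo, src_hi = p1$hi, dup_of = NA_character_,
          chim_kind = kinds[k], true_breakpoint = bp)
        c_int[[k]] <- tibble(
          contig_id = rep(cid, 2), ref_id = c(p1$ref_id, p2$ref_id),
          lo = c(p1$lo, p2$lo), hi = c(p1$hi, p2$hi))
      }
      contigs <- bind_rows(contigs, bind_rows(c_ctg))
      hits <- c(hits, c_hit)
      truth_contigs <- bind_rows(truth_contigs, bind_rows(c_tru))
      intervals <- bind_rows(intervals, bind_rows(c_int))
    }

    hits <- bind_rows(hits)

    # --- optional hit noise -------------------------------------------
    if (!is.null(noise)) {
      jit <- noise$identity_jitter %||% 5
      trim_max <- noise$trim_max %||% 20
      decoy_rate <- noise$decoy_rate %||% 0.05
      n <- nrow(hits)
      hits$pct_identity <- pmax(70, 100 - abs(rnorm(n, 0, jit)))
      if (trim_max > 0) {
        t_lo <- sample.int(trim_max + 1L, n, replace = TRUE) - 1L
        t_hi <- sample.int(trim_max + 1L, n, replace = TRUE) - 1L
        len <- hits$q_end - hits$q_start + 1L
        keep_room <- pmax(0L, len - 60L)  # never shrink below 60 bases
        t_lo <- pmin(t_lo, keep_room %/% 2L)
        t_hi <- pmin(t_hi, keep_room %/% 2L)
        hits$q_start <- hits$q_start + t_lo
        hits$q_end <- hits$q_end - t_hi
        fwd <- hits$s_start <= hits$s_end
        hits$s_start <- hits$s_start + ifelse(fwd, t_lo, -t_lo)
        hits$s_end <- hits$s_end + ifelse(fwd, -t_hi, t_hi)
        hits$aln_length <- hits$q_end - hits$q_start + 1L
      }
      n_decoy <- round(decoy_rate * nrow(contigs))
      if (n_decoy > 0) {
        dq <- sample(contigs$id, n_decoy, replace = TRUE)
        dr <- sample(reference$id, n_decoy, replace = TRUE)
        dlen <- sample(40:90, n_decoy, replace = TRUE)
        qs <- pmax(1L, nchar(setNames(contigs$sequence, contigs$id))[dq] -
                     dlen)
        ss <- purrr::map2_int(dr, dlen,
                              ~sample.int(max(1L, ref_len[[.x]] - .y), 1))
        decoys <- tibble(
          query_id = dq, subject_id = dr,
          pct_identity = runif(n_decoy, 20, 29.5),
          aln_length = as.integer(dlen), mismatches = as.integer(dlen %/% 3),
          gap_opens = 0L, q_start = as.integer(qs),
          q_end = as.integer(qs + dlen - 1L), s_start = as.integer(ss),
          s_end = as.integer(ss + dlen - 1L), evalue = 1e-3,
          bitscore = 40)
        hits <- bind_rows(hits, decoys)
      }
    }

    # --- realized truth ------------------------------------------------
    ref_truth <- intervals |>
      group_by(.data$ref_id) |>
      summarise(covered_all = union_len_naive(.data$lo, .data$hi),
                .groups = "drop")
    best_single <- intervals |>
      group_by(.data$ref_id, .data$contig_id) |>
      summarise(covered = union_len_naive(.data$lo, .data$hi),
                .groups = "drop") |>
      group_by(.data$ref_id) |>
      summarise(covered_best_single = max(.data$covered), .groups = "drop")
    references <- tibble(ref_id = reference$id,
                         ref_length = unname(ref_len)) |>
      left_join(ref_truth, by = "ref_id") |>
      left_join(best_single, by = "ref_id") |>
      mutate(covered_all = dplyr::coalesce(.data$covered_all, 0) /
               .data$ref_length,
             covered_best_single =
               dplyr::coalesce(.data$covered_best_single, 0) /
               .data$ref_length)

    n_chim_real <- sum(truth_contigs$role == "chimera")
    n_nonred <- n_frag + n_chim_real
    list(
      contigs = contigs,
      hits = hits,
      truth = list(
        contigs = truth_contigs,
        references = references,
        chimera_rate = n_chim_real / n_nonred,
        n_fragments = n_frag,
        n_duplicates = sum(truth_contigs$role == "duplicate")
      )
    )
  })
}

#' Check a simulated hit table against its sequences
#'
#' Verifies that every idealized (identity-100) hit interval is an exact
#' image of its source: the contig substring equals the reference substring
#' (reverse-complemented for reverse-orientation hits).
#'
#' @param sim a [simulate_assembly()] result.
#' @param reference the reference tibble the assembly was simulated from.
#' @return `TRUE` invisibly; mismatches are an error.
#' @export
validate_sim_hits <- function(sim, reference) {
  h <- normalize_hits(filter(sim$hits, .data$pct_identity == 100))
  ctg <- setNames(sim$contigs$sequence, sim$contigs$id)
  rf <- setNames(reference$sequence, reference$id)
  qs <- substring(ctg[h$query_id], h$q_lo + 1, h$q_hi)
  ss <- substring(rf[h$subject_id], h$s_lo + 1, h$s_hi)
  ss[h$s_strand == "-"] <- revcomp(ss[h$s_strand == "-"])
  bad <- which(qs != ss)
  if (length(bad)) {
    stop("hit/sequence mismatch for contig(s): ",
         paste(unique(h$query_id[head(bad, 5)]), collapse = ", "))
  }
  invisible(TRUE)
}
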