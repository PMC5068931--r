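# Independent brute-force oracles used to cross-check the optimized
# implementations. These deliberately share no code with the package
# internals: plain loops, exhaustive candidate checks.

# N50 by checking every candidate length L.
oracle_n50 <- function(lengths) {
  half <- sum(lengths) / 2
  # largest L whose at-least-L tail still holds half the bases
  cand <- sort(unique(lengths))
  keep <- cand[vapply(cand, function(L) sum(lengths[lengths >= L]) >= half,
                      logical(1))]
  max(keep)
}

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# Quadratic both-strand dedup: returns retained ids.
oracle_dedup_ids <- function(ids, seqs) {
  n <- length(seqs)
  rc <- vapply(seqs, oracle_revcomp, character(1), USE.NAMES = FALSE)
  # order candidates the way the contract demands: longest first, then id
  ord <- order(-nchar(seqs), ids)
  kept <- integer(0)
  for (i in ord) {
    contained <- FALSE
    for (j in kept) {
      if (grepl(seqs[i], seqs[j], fixed = TRUE) ||
          grepl(rc[i], seqs[j], fixed = TRUE)) {
        contained <- TRUE
        break
      }
    }
    if (!contained) kept <- c(kept, i)
  }
  sort(ids[kept])
}

# Interval-union length by position marking (0-based half-open).
oracle_union_length <- function(lo, hi) {
  if (length(lo) == 0) return(0)
  covered <- logical(max(hi))
  for (k in seq_along(lo)) {
    if (hi[k] > lo[k]) covered[(lo[k] + 1):hi[k]] <- TRUE
  }
  sum(covered)
}

# ---- Nei-Gojobori brute force ---------------------------------------

oracle_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
}

oracle_sites <- function(codon) {
  gc <- oracle_code()
  bases <- c("A", "C", "G", "T")
  p <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) {
    for (b in bases) {
      if (b == p[pos]) next
      q <- p
      q[pos] <- b
      m <- paste(q, collapse = "")
      if (gc[m] != "*" && gc[m] == gc[codon]) s <- s + 1 / 3
    }
  }
  c(s = s, n = 3 - s)
}

# All minimal pathways by recursive DFS; stop-passing pathways dropped.
oracle_diffs <- function(ca, cb) {
  gc <- oracle_code()
  a <- strsplit(ca, "")[[1]]
  b <- strsplit(cb, "")[[1]]
  walk <- function(cur, remaining) {
    if (length(remaining) == 0) return(list(c(0, 0)))
    out <- list()
    for (pos in remaining) {
      nxt <- cur
      nxt[pos] <- b[pos]
      codon <- paste(nxt, collapse = "")
      if (gc[codon] == "*") next
      step <- if (gc[paste(cur, collapse = "")] == gc[codon]) c(1, 0) else c(0, 1)
      for (tail_counts in walk(nxt, setdiff(remaining, pos))) {
        out <- c(out, list(step + tail_counts))
      }
    }
    out
  }
  paths <- walk(a, which(a != b))
  if (length(paths) == 0) return(NULL)  # fully stop-blocked pair
  m <- Reduce(`+`, paths) / length(paths)
  c(sd = m[1], nd = m[2])
}

oracle_kaks <- function(seq_a, seq_b) {
  ncod <- nchar(seq_a) %/% 3
  S <- 0; N <- 0; Sd <- 0; Nd <- 0
  for (k in seq_len(ncod)) {
    ca <- substr(seq_a, 3 * k - 2, 3 * k)
    cb <- substr(seq_b, 3 * k - 2, 3 * k)
    sa <- oracle_sites(ca); sb <- oracle_sites(cb)
    S <- S + (sa["s"] + sb["s"]) / 2
    N <- N + (sa["n"] + sb["n"]) / 2
    d <- oracle_diffs(ca, cb)
    if (!is.null(d)) {
      Sd <- Sd + d[["sd"]]; Nd <- Nd + d[["nd"]]
    }
  }
  S <- unname(S); N <- unname(N)
  pS <- Sd / S; pN <- Nd / N
  jc <- function(p) if (p < 0.75) -0.75 * log(1 - 4 * p / 3) else NA_real_
  list(S = unname(S), N = unname(N), Sd = unname(Sd), Nd = unname(Nd),
       pS = unname(pS), pN = unname(pN), Ks = jc(pS), Ka = jc(pN))
}

# Random sense-codon CDS for oracle comparisons.
random_cds <- function(n_codons) {
  gc <- oracle_code()
  sense <- names(gc)[gc != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

# Random nucleotide sequence tibble for round-trip tests.
random_seqset <- function(n, len_range = c(10, 80)) {
  tibble::tibble(
    id = sprintf("s%03d", seq_len(n)),
    sequence = vapply(seq_len(n), function(i) {
      len <- len_range[1] + sample.int(len_range[2] - len_range[1] + 1, 1) - 1
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    }, character(1)),
    description = ifelse(seq_len(n) %% 2 == 0, "even record", "")
  )
}
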