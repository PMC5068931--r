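# Pairwise synonymous/nonsynonymous divergence by the counting method of
# Nei & Gojobori: per-codon synonymous/nonsynonymous site fractions, codon
# differences classified along all minimal mutational pathways with equal
# weights (pathways through stop codons excluded), proportions corrected
# for multiple hits with the Jukes-Cantor formula.

codon_env <- new.env(parent = emptyenv())

genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}

translate_codon <- function(codon) {
  genetic_code()[codon]
}

is_stop <- function(codon) {
  unname(genetic_code()[codon] == "*")
}

NT <- c("A", "C", "G", "T")

#' Synonymous and nonsynonymous site fractions of one codon
#'
#' Each codon position contributes the fraction of its three possible
#' single-nucleotide changes that are synonymous to the synonymous site
#' count `s`, and the remainder to `n`; `s + n = 3`. Changes creating a
#' stop codon count as nonsynonymous under the default convention, or are
#' dropped from the position's denominator with
#' `stop_handling = "exclude"` (either way `s + n = 3`).
#'
#' @param codon 3-letter string over A/C/G/T, not a stop codon.
#' @param stop_handling `"nonsyn"` (default) or `"exclude"`.
#' @return named numeric vector `c(s = , n = )`.
#' @export
count_sites <- function(codon, stop_handling = c("nonsyn", "exclude")) {
  stop_handling <- match.arg(stop_handling)
  tab <- site_table(stop_handling)
  if (!codon %in% rownames(tab)) {
    stop("invalid or stop codon: ", codon)
  }
  c(s = tab[codon, "s"], n = tab[codon, "n"])
}

# Site fractions for all 61 sense codons, cached per convention.
site_table <- function(stop_handling) {
  key <- paste0("sites_", stop_handling)
  if (!is.null(codon_env[[key]])) return(codon_env[[key]])
  gc <- genetic_code()
  sense <- names(gc)[gc != "*"]
  tab <- matrix(0, nrow = length(sense), ncol = 2,
                dimnames = list(sense, c("s", "n")))
  for (codon in sense) {
    parts <- strsplit(codon, "")[[1]]
    s <- 0
    for (pos in 1:3) {
      alts <- setdiff(NT, parts[pos])
      mut <- vapply(alts, function(b) {
        p <- parts; p[pos] <- b; paste(p, collapse = "")
      }, character(1))
      syn <- sum(gc[mut] == gc[codon] & gc[mut] != "*")
      denom <- if (stop_handling == "exclude") sum(gc[mut] != "*") else 3L
      if (denom > 0) s <- s + syn / denom
    }
    tab[codon, "s"] <- s
    tab[codon, "n"] <- 3 - s
  }
  codon_env[[key]] <- tab
  tab
}

all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in all_perms(v[-i])) out <- c(out, list(c(v[i], p)))
  }
  out
}

#' Synonymous and nonsynonymous differences between two codons
#'
#' All minimal mutational pathways between the codons (one substitution per
#' step) are enumerated; each step is synonymous when it preserves the
#' amino acid. Pathways passing through a stop codon are excluded, and the
#' per-step classifications are averaged over the remaining pathways with
#' equal weights. `sd + nd` equals the number of differing positions. If
#' every pathway passes through a stop (only possible at 2-3 differences),
#' all pathways are used as a fallback.
#'
#' @param codon_a,codon_b 3-letter codons over A/C/G/T, neither a stop.
#' @return named numeric vector `c(sd = , nd = )`.
#' @export
count_differences <- function(codon_a, codon_b) {
  gc <- genetic_code()
  if (!codon_a %in% names(gc) || gc[codon_a] == "*") {
    stop("invalid or stop codon: ", codon_a)
  }
  if (!codon_b %in% names(gc) || gc[codon_b] == "*") {
    stop("invalid or stop codon: ", codon_b)
  }
  a <- strsplit(codon_a, "")[[1]]
  b <- strsplit(codon_b, "")[[1]]
  diffpos <- which(a != b)
  if (length(diffpos) == 0) return(c(sd = 0, nd = 0))
  paths <- all_perms(diffpos)
  classify <- function(order) {
    cur <- a
    sd <- 0; nd <- 0
    for (pos in order) {
      nxt <- cur
      nxt[pos] <- b[pos]
      cfrom <- paste(cur, collapse = "")
      cto <- paste(nxt, collapse = "")
      if (gc[cto] == "*" && !identical(nxt, b)) return(NULL) # stop intermediate
      if (gc[cfrom] == gc[cto]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  counted <- purrr::compact(purrr::map(paths, classify))
  if (length(counted) == 0) {
    # every pathway blocked by a stop intermediate: fall back to all paths
    counted <- purrr::map(paths, function(order) {
      cur <- a; sd <- 0; nd <- 0
      for (pos in order) {
        nxt <- cur; nxt[pos] <- b[pos]
        same <- gc[paste(cur, collapse = "")] == gc[paste(nxt, collapse = "")]
        if (isTRUE(same)) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(sd, nd)
    })
  }
  m <- colMeans(do.call(rbind, counted))
  c(sd = m[[1]], nd = m[[2]])
}

jukes_cantor <- function(p) {
  ifelse(p < 0.75, -0.75 * log(1 - 4 * p / 3), NA_real_)
}

#' Pairwise Ka/Ks of two aligned coding sequences
#'
#' Nei-Gojobori counting with equal pathway weights and Jukes-Cantor
#' correction: synonymous (S) and nonsynonymous (N) site counts averaged
#' over the two sequences, differences (Sd, Nd) summed over codon pairs,
#' proportions pS = Sd/S and pN = Nd/N corrected as
#' `d = -3/4 ln(1 - 4p/3)`. Codons containing gaps or ambiguous bases in
#' either sequence, and codon pairs involving a stop codon, are dropped
#' pairwise. A Ka/Ks below 1 indicates purifying selection; values near 1,
#' relaxed constraint.
#'
#' @param seq_a,seq_b aligned coding sequences (equal length, in frame).
#' @param stop_handling site-counting convention, see [count_sites()].
#' @return an object of class `kaks_result`: list with `n_codons_used`,
#'   `S`, `N`, `Sd`, `Nd`, `pS`, `pN`, `Ks`, `Ka`, `ratio` (NA when
#'   undefined: `Ks` 0 or a proportion >= 3/4). Has [tidy()] and
#'   [glance()] methods.
#' @export
kaks <- function(seq_a, seq_b, stop_handling = c("nonsyn", "exclude")) {
  stop_handling <- match.arg(stop_handling)
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (nchar(seq_a) != nchar(seq_b)) {
    stop("aligned sequences must have equal length")
  }
  ncod <- nchar(seq_a) %/% 3
  if (ncod == 0) stop("no complete codons in the alignment")
  starts <- 3 * (seq_len(ncod) - 1) + 1
  cods_a <- substring(seq_a, starts, starts + 2)
  cods_b <- substring(seq_b, starts, starts + 2)
  gc <- genetic_code()
  clean <- grepl("^[ACGT]{3}$", cods_a) & grepl("^[ACGT]{3}$", cods_b)
  usable <- clean & !is_stop_safe(cods_a, gc) & !is_stop_safe(cods_b, gc)
  cods_a <- cods_a[usable]; cods_b <- cods_b[usable]
  n_used <- length(cods_a)
  if (n_used == 0) stop("no usable codons after pairwise deletion")

  tab <- site_table(stop_handling)
  S <- (sum(tab[cods_a, "s"]) + sum(tab[cods_b, "s"])) / 2
  N <- (sum(tab[cods_a, "n"]) + sum(tab[cods_b, "n"])) / 2
  diffs <- purrr::map2(cods_a, cods_b, count_differences)
  Sd <- sum(purrr::map_dbl(diffs, "sd"))
  Nd <- sum(purrr::map_dbl(diffs, "nd"))
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  Ks <- jukes_cantor(pS)
  Ka <- jukes_cantor(pN)
  ratio <- if (!is.na(Ks) && !is.na(Ka) && Ks > 0) Ka / Ks else NA_real_
  structure(
    list(n_codons_used = n_used, S = S, N = N, Sd = Sd, Nd = Nd,
         pS = pS, pN = pN, Ks = Ks, Ka = Ka, ratio = ratio,
         stop_handling = stop_handling),
    class = "kaks_result"
  )
}

is_stop_safe <- function(codons, gc) {
  out <- rep(FALSE, length(codons))
  known <- codons %in% names(gc)
  out[known] <- gc[codons[known]] == "*"
  out
}

#' @export
print.kaks_result <- function(x, ...) {
  cat("Nei-Gojobori pairwise Ka/Ks\n")
  cat(sprintf("  %d codons: S = %.2f, N = %.2f, Sd = %.2f, Nd = %.2f\n",
              x$n_codons_used, x$S, x$N, x$Sd, x$Nd))
  cat(sprintf("  pS = %.4f, pN = %.4f, Ks = %s, Ka = %s, Ka/Ks = %s\n",
              x$pS, x$pN, fmt_na(x$Ks), fmt_na(x$Ka), fmt_na(x$ratio)))
  invisible(x)
}

fmt_na <- function(v) if (is.na(v)) "undefined" else sprintf("%.4f", v)

#' Ka/Ks from a two-record aligned FASTA
#'
#' @param path FASTA with exactly two aligned CDS records.
#' @param ... passed to [kaks()].
#' @return a `kaks_result`.
#' @export
kaks_from_fasta <- function(path, ...) {
  seqs <- read_fasta(path, alphabet = "nucleotide")
  if (nrow(seqs) != 2) {
    stop("expected exactly 2 aligned records, found ", nrow(seqs))
  }
  kaks(seqs$sequence[1], seqs$sequence[2], ...)
}
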