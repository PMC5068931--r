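# FASTA input/output. Sequence sets are plain tibbles with columns
# id, sequence, description so they compose with dplyr; Biostrings does the
# actual file handling.

IUPAC_NT <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
              "B", "D", "H", "V", "N")

#' Read a FASTA file into a sequence tibble
#'
#' Returns one row per record with the id (header token before the first
#' whitespace), the full sequence (multi-line records concatenated, stored
#' uppercase) and the remainder of the header line as `description`.
#'
#' @param path path to a FASTA file.
#' @param alphabet `"nucleotide"` (default) or `"protein"`. Nucleotide
#'   sequences are validated against the IUPAC nucleotide alphabet.
#' @return a tibble with columns `id`, `sequence`, `description` and an
#'   `alphabet` attribute. Record order is preserved.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">c1 demo", "ACGT", "ACGT"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path, alphabet = c("nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  headers <- names(ss)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(ss))
  names(seqs) <- NULL
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (any(!nzchar(seqs))) {
    stop("empty sequence record(s): ",
         paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  if (alphabet == "nucleotide" && length(seqs)) {
    bad <- stringr::str_locate(seqs, paste0("[^", paste(IUPAC_NT, collapse = ""), "-]"))[, 1]
    if (any(!is.na(bad))) {
      i <- which(!is.na(bad))[1]
      stop("non-nucleotide character in record '", ids[i],
           "' at position ", bad[i])
    }
  }
  out <- tibble(id = ids, sequence = seqs, description = desc)
  attr(out, "alphabet") <- alphabet
  out
}

#' Write a sequence tibble to FASTA
#'
#' @param seqs tibble with columns `id`, `sequence` and optionally
#'   `description`.
#' @param path output path.
#' @param line_width characters of sequence per line (default 60).
#' @return `path`, invisibly. `read_fasta(write_fasta(x, p))` reproduces `x`.
#' @export
write_fasta <- function(seqs, path, line_width = 60) {
  stopifnot(is.data.frame(seqs), all(c("id", "sequence") %in% names(seqs)),
            line_width >= 1)
  ss <- Biostrings::BStringSet(seqs$sequence)
  desc <- if ("description" %in% names(seqs)) seqs$description else ""
  names(ss) <- ifelse(nzchar(desc), paste(seqs$id, desc), seqs$id)
  Biostrings::writeXStringSet(ss, path, width = as.integer(line_width))
  invisible(path)
}
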