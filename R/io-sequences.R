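#' Read and write FASTA files
#'
#' Sequences are carried through the package as a tibble with one row per
#' record and columns `id` and `seq`. Sequence text is uppercased on read and
#' restricted to the DNA alphabet `A,C,G,T,N`. Record ids are the first
#' whitespace-delimited token of each header and must be unique.
#'
#' @param path Path to a FASTA file.
#' @return `read_fasta()` returns a tibble with columns `id` (character) and
#'   `seq` (character). `write_fasta()` invisibly returns `path`.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' write_fasta(tibble::tibble(id = "a", seq = "ACGT"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  ss <- Biostrings::readBStringSet(path)
  ids <- stringr::word(names(ss), 1)
  seqs <- toupper(as.character(ss))
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate FASTA id(s): ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  if (any(nchar(seqs) == 0)) {
    abort(paste0("empty sequence for id(s): ",
                 paste(ids[nchar(seqs) == 0], collapse = ", ")))
  }
  bad <- stringr::str_detect(seqs, "[^ACGTN]")
  if (any(bad)) {
    abort(paste0("non-DNA characters in sequence(s): ",
                 paste(ids[bad], collapse = ", ")))
  }
  tibble(id = unname(ids), seq = unname(seqs))
}

#' @param seqs A sequence tibble (`id`, `seq`).
#' @param line_width Characters per sequence line on disk.
#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path, line_width = 70L) {
  validate_seqs(seqs)
  ss <- Biostrings::BStringSet(setNames(seqs$seq, seqs$id))
  Biostrings::writeXStringSet(ss, path, width = line_width)
  invisible(path)
}

validate_seqs <- function(seqs) {
  stopifnot(is.data.frame(seqs), all(c("id", "seq") %in% names(seqs)))
  if (anyDuplicated(seqs$id)) {
    abort(paste0("duplicate sequence id(s): ",
                 paste(unique(seqs$id[duplicated(seqs$id)]), collapse = ", ")))
  }
  if (any(nchar(seqs$seq) == 0)) abort("empty sequence not allowed")
  invisible(seqs)
}

#' Sequence lengths of a sequence tibble
#'
#' @param seqs A sequence tibble (`id`, `seq`).
#' @return Named integer vector of sequence lengths.
#' @export
seq_lengths <- function(seqs) {
  setNames(nchar(seqs$seq), seqs$id)
}

#' Reverse complement of DNA strings
#'
#' Vectorised over `x`; `N` is self-complementary.
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTN", "TGCAN", x))
}

# random DNA, used throughout the simulator
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
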