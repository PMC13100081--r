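#' Read a FASTA file into a named character vector
#'
#' Thin wrapper over [Biostrings::readBStringSet()]. Sequence names are the
#' first whitespace-delimited token of each header; sequences are upper-cased.
#'
#' @param path FASTA file (plain text or gzip).
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  assert_file(path, "FASTA")
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  seqs
}

#' Write a named character vector as FASTA
#' @param seqs Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 70L)
  invisible(path)
}

#' Build a reference-proteome database with a substring-membership index
#'
#' The self-similarity veto needs fast exact-substring lookup over the whole
#' proteome. Sequences are concatenated with a sentinel (`#`, outside the
#' amino-acid alphabet) so one fixed-string search answers membership.
#'
#' @param sequences Named character vector of amino-acid sequences
#'   (20 standard residues plus `X` and `*`), or a path to a protein FASTA.
#' @return A `neo_proteome` object.
#' @export
build_proteome <- function(sequences) {
  if (is.character(sequences) && length(sequences) == 1L &&
      file.exists(sequences)) {
    sequences <- read_fasta(sequences)
  }
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  sequences <- toupper(sequences)
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX*]", sequences)
  if (any(bad)) {
    neo_stop(sprintf("proteome sequence(s) with invalid residues: %s",
                     paste(head(names(sequences)[bad], 5L), collapse = ", ")))
  }
  structure(
    list(sequences = sequences,
         index = paste(sequences, collapse = "#")),
    class = "neo_proteome"
  )
}

#' Exact self-similarity check against the reference proteome
#'
#' A candidate peptide that occurs verbatim anywhere in the reference proteome
#' is indistinguishable from self and is assigned priority zero downstream.
#'
#' @param peptide Character vector of peptides.
#' @param proteome A `neo_proteome` from [build_proteome()].
#' @return Logical vector: `TRUE` where the peptide is an exact substring of
#'   any proteome sequence.
#' @export
self_similarity <- function(peptide, proteome) {
  stopifnot(inherits(proteome, "neo_proteome"))
  vapply(toupper(peptide), function(p) {
    nzchar(p) && grepl(p, proteome$index, fixed = TRUE)
  }, TRUE, USE.NAMES = FALSE)
}

#' @export
print.neo_proteome <- function(x, ...) {
  cat(sprintf("<neo_proteome> %d sequences, %s residues\n",
              length(x$sequences),
              format(sum(nchar(x$sequences)), big.mark = ",")))
  invisible(x)
}
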