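#' Translate a coding sequence into protein
#'
#' Standard-genetic-code translation used by the frameshift and fusion-junction
#' peptide paths. Translation begins at the first base, stops at (and excludes)
#' the first stop codon, ignores a trailing partial codon, and renders any
#' codon containing a non-ACGT base as `X`.
#'
#' @param cds Nucleotide string (case-insensitive).
#' @return Amino-acid string (possibly empty).
#' @examples
#' translate_cds("ATGGCC")    # "MA"
#' translate_cds("ATGTAAGCC") # "M" (stop truncates)
#' @export
translate_cds <- function(cds) {
  stopifnot(is.character(cds), length(cds) == 1L)
  cds <- toupper(cds)
  n_codon <- nchar(cds) %/% 3L
  if (n_codon == 0L) return("")
  codons <- substring(cds, 3L * seq_len(n_codon) - 2L, 3L * seq_len(n_codon))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  stop_at <- match("*", aa)
  if (!is.na(stop_at)) aa <- aa[seq_len(stop_at - 1L)]
  paste(aa, collapse = "")
}

#' Reverse-translate helpers for fixtures (codon sampling)
#'
#' Sample a random CDS of `n_codons` codons with no internal stop codon,
#' optionally ending with a stop. Used by the synthetic cohort generator.
#' @keywords internal
random_cds <- function(n_codons, terminal_stop = FALSE) {
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  body <- sample(sense, n_codons, replace = TRUE)
  if (terminal_stop) body <- c(body, sample(c("TAA", "TAG", "TGA"), 1L))
  paste(body, collapse = "")
}
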