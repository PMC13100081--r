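# Pluggable peptide-MHC %Rank providers. The engine never re-implements a
# binding predictor: real predictions are imported from NetMHCpan-style
# tabular output, and a deterministic stub stands in for tests and the
# synthetic cohort. Every provider must be a pure function of
# (peptide, allele).

.predictors <- new.env(parent = emptyenv())

#' Register / fetch a binding predictor by name
#'
#' A predictor is a function `(peptides, alleles) -> data.table(peptide,
#' allele, rank_percent)` that is deterministic in its inputs.
#'
#' @param name Provider name.
#' @param fun Predictor function.
#' @export
register_predictor <- function(name, fun) {
  stopifnot(is.character(name), is.function(fun))
  assign(name, fun, envir = .predictors)
  invisible(name)
}

#' @rdname register_predictor
#' @export
get_predictor <- function(name) {
  if (!exists(name, envir = .predictors, inherits = FALSE)) {
    neo_stop(sprintf("unknown binding predictor '%s' (registered: %s)",
                     name, paste(ls(.predictors), collapse = ", ")))
  }
  get(name, envir = .predictors, inherits = FALSE)
}

# Deterministic polynomial rolling hash (exact in double arithmetic).
str_hash <- function(s, mod = 1000003) {
  vapply(s, function(x) {
    h <- 0
    for (code in utf8ToInt(x)) h <- (h * 31 + code) %% mod
    h
  }, 1, USE.NAMES = FALSE)
}

aa_alphabet <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Anchor residue pair of the stub predictor for an allele
#'
#' The stub assigns each allele a preferred (position 2, C-terminus) residue
#' pair derived from a stable digest of the allele name; peptides matching
#' both anchors receive the motif bonus. Exposed so tests and the synthetic
#' cohort can plant strong binders deliberately.
#'
#' @param allele Normalized allele string(s).
#' @return 2-column character matrix (`p2`, `cterm`).
#' @export
stub_anchor_pair <- function(allele) {
  h <- str_hash(allele)
  cbind(p2 = aa_alphabet[h %% 20 + 1],
        cterm = aa_alphabet[(h %/% 20) %% 20 + 1])
}

#' Deterministic stub %Rank predictor
#'
#' Produces a pseudo-rank in (0, 100] from a stable digest of
#' (peptide, allele): uniform-looking, reproducible across sessions and
#' platforms, with no external tool. Peptides whose position-2 and C-terminal
#' residues match the allele's [stub_anchor_pair()] have their rank
#' multiplied by `motif_bonus` (default 1/200), planting strong binders.
#'
#' @param peptides Character vector of 8-11-mer peptides.
#' @param alleles Character vector of normalized alleles; predictions are
#'   made for every peptide x allele combination.
#' @param motif_bonus Multiplicative rank bonus for anchor-matched peptides,
#'   in (0, 1].
#' @return `data.table` (`peptide`, `allele`, `rank_percent`) of class
#'   `neo_binding`.
#' @export
stub_predict <- function(peptides, alleles, motif_bonus = 0.005) {
  stopifnot(motif_bonus > 0, motif_bonus <= 1)
  bad <- nchar(peptides) < 8L | nchar(peptides) > 11L |
    grepl("[^ACDEFGHIKLMNPQRSTVWY]", peptides)
  if (any(bad)) {
    neo_stop(sprintf("invalid peptide(s) for prediction: %s",
                     paste(head(peptides[bad], 3L), collapse = ", ")))
  }
  grid <- data.table::CJ(peptide = unique(peptides),
                         allele = unique(normalize_hla(alleles)),
                         sorted = FALSE)
  h <- str_hash(paste0(grid$peptide, "|", grid$allele))
  rank <- (h %% 999983 + 1) / 999983 * 100   # in (0, 100]
  anchors <- stub_anchor_pair(grid$allele)
  hit <- substr(grid$peptide, 2L, 2L) == anchors[, "p2"] &
    substr(grid$peptide, nchar(grid$peptide), nchar(grid$peptide)) ==
      anchors[, "cterm"]
  rank[hit] <- rank[hit] * motif_bonus
  out <- data.table::data.table(peptide = grid$peptide, allele = grid$allele,
                                rank_percent = rank)
  data.table::setattr(out, "class", c("neo_binding", class(out)))
  out[]
}

#' Write binding scores in the tabular interchange dialect
#' @param scores `neo_binding` table.
#' @param path Output path.
#' @export
write_predictions <- function(scores, path) {
  assert_cols(scores, c("peptide", "allele", "rank_percent"), "binding scores")
  data.table::fwrite(
    data.table::as.data.table(scores)[, .(peptide, allele, rank_percent)],
    path, sep = "\t", eol = "\n")
  invisible(path)
}

#' Import peptide-MHC %Rank predictions (NetMHCpan-4.x tabular dialect)
#'
#' Accepts a tab-separated file with peptide, allele and %Rank columns
#' (`peptide`/`Peptide`, `allele`/`MHC`/`HLA`, and
#' `rank_percent`/`%Rank`/`EL_Rank`/`Rank`/`BA_Rank`). Conflicting duplicate
#' rows for the same (peptide, allele) pair are a hard error; exact
#' duplicates collapse. When `expected_pairs` is given, missing pairs are
#' reported via a warning and the `missing` attribute.
#'
#' @param path Predictions file.
#' @param expected_pairs Optional `data.frame` with columns
#'   `peptide`, `allele`.
#' @return `neo_binding` table; attribute `missing` holds unmatched expected
#'   pairs.
#' @export
import_predictions <- function(path, expected_pairs = NULL) {
  assert_file(path, "predictions file")
  dt <- data.table::fread(path, sep = "\t")
  find_col <- function(cands) {
    hit <- intersect(cands, names(dt))
    if (!length(hit)) {
      neo_stop(sprintf("predictions file lacks a column among: %s",
                       paste(cands, collapse = ", ")))
    }
    hit[1]
  }
  pep <- find_col(c("peptide", "Peptide"))
  hla <- find_col(c("allele", "MHC", "HLA", "Allele"))
  rnk <- find_col(c("rank_percent", "%Rank", "EL_Rank", "Rank", "BA_Rank",
                    "%Rank_EL", "%Rank_BA"))
  out <- data.table::data.table(
    peptide = as.character(dt[[pep]]),
    allele = normalize_hla(as.character(dt[[hla]])),
    rank_percent = as.numeric(dt[[rnk]])
  )
  if (anyNA(out$rank_percent) || any(out$rank_percent <= 0)) {
    neo_stop("predictions file has missing or non-positive %Rank values")
  }
  out <- unique(out)
  dup <- duplicated(out[, .(peptide, allele)])
  if (any(dup)) {
    neo_stop(sprintf("conflicting %%Rank values for pair(s): %s",
                     paste(head(paste0(out$peptide[dup], "/", out$allele[dup]),
                                3L), collapse = ", ")))
  }
  missing <- NULL
  if (!is.null(expected_pairs)) {
    ep <- data.table::as.data.table(expected_pairs)[, .(peptide, allele)]
    ep[, allele := normalize_hla(allele)]
    missing <- ep[!out, on = c("peptide", "allele")]
    if (nrow(missing)) {
      warning(sprintf("%d expected (peptide, allele) pair(s) missing from predictions",
                      nrow(missing)), call. = FALSE)
    }
  }
  data.table::setattr(out, "class", c("neo_binding", class(out)))
  data.table::setattr(out, "missing", missing)
  out[]
}

#' Classify a %Rank into strong / weak / non-binder
#'
#' Strong binders have rank below 0.5; weak binders lie in \[0.5, 2.0\];
#' anything above 2.0 is a non-binder. The boundaries are configurable but
#' the defaults are the conventional NetMHCpan thresholds.
#'
#' @param rank_percent Positive numeric vector.
#' @param strong,weak Class boundaries (strong < weak).
#' @return Character vector in `c("strong", "weak", "non_binder")`.
#' @export
classify_binder <- function(rank_percent, strong = 0.5, weak = 2.0) {
  stopifnot(strong < weak)
  if (any(is.na(rank_percent) | rank_percent <= 0)) {
    neo_stop("rank_percent must be > 0")
  }
  data.table::fcase(
    rank_percent < strong, "strong",
    rank_percent <= weak, "weak",
    default = "non_binder"
  )
}
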