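# The multi-component neoepitope priority score. Every component is bounded,
# the composite is their product scaled to 0-100, and two hard vetoes exist:
# exact self-similarity and the expression gate.

#' Logistic down-weighting of the binding %Rank
#'
#' `L(x) = 1 / (1 + exp(slope * (x - inflection)))` with slope 5 and
#' inflection at 2 percent rank: strong binders (low rank) approach 1,
#' and peptides above 2 percent are rapidly down-weighted rather than hard
#'-excluded.
#'
#' @param rank_percent Positive numeric vector of %Rank values.
#' @param slope,inflection Transform parameters.
#' @return Values in (0, 1).
#' @export
logistic_rank_weight <- function(rank_percent, slope = 5, inflection = 2) {
  if (any(is.na(rank_percent) | rank_percent <= 0)) {
    neo_stop("rank_percent must be > 0")
  }
  1 / (1 + exp(slope * (rank_percent - inflection)))
}

#' Hyperbolic-tangent expression component
#'
#' `tanh(value / scale)`: 0 at zero expression, saturating toward 1. The
#' scale sets where the component has gradient -- default 10 for gene TPM
#' and 2 for fusion FFPM, so typical expressed candidates (1-50 TPM, 1-10
#' FFPM) are spread rather than saturated. The minimum-expression gate is a
#' separate veto ([expression_gate()]).
#'
#' @param value Non-negative expression value(s).
#' @param unit `"TPM"` or `"FFPM"` (selects the default scale).
#' @param scales Named numeric vector of scales per unit.
#' @return Values in \[0, 1).
#' @export
expression_component <- function(value, unit = "TPM",
                                 scales = c(TPM = 10, FFPM = 2)) {
  if (any(is.na(value) | value < 0)) neo_stop("expression value must be >= 0")
  sc <- unname(scales[unit])
  if (anyNA(sc)) neo_stop(sprintf("no tanh scale for unit '%s'",
                                  paste(unique(unit[is.na(sc)]), collapse = ", ")))
  tanh(value / sc)
}

#' Minimum-expression gate
#'
#' SNV/indel/frameshift candidates pass iff their source gene's TPM is at
#' least `min_tpm` (default 1, approximating sufficient antigen supply);
#' fusion candidates pass iff the fusion's FFPM reaches `min_ffpm` (default
#' 1). A candidate whose gene is absent from the abundance table fails the
#' gate.
#'
#' @param value Expression value (TPM or FFPM); `NA` fails.
#' @param source_type Candidate source (`"fusion"` uses the FFPM minimum).
#' @param min_tpm,min_ffpm Gate thresholds.
#' @return Logical vector.
#' @export
expression_gate <- function(value, source_type, min_tpm = 1, min_ffpm = 1) {
  thr <- ifelse(source_type == "fusion", min_ffpm, min_tpm)
  !is.na(value) & value >= thr
}

#' Clonality component
#'
#' The variant allele frequency is used directly as a linear clonality
#' weight, deprioritizing subclonal events. Fusions, whose VAF is not
#' measurable from RNA, are treated as clonal drivers (weight 1).
#'
#' @param vaf VAF in \[0, 1\] (`NA` allowed for fusions).
#' @param source_type Candidate source.
#' @return Values in \[0, 1\].
#' @export
clonality_component <- function(vaf, source_type) {
  out <- ifelse(source_type == "fusion", 1, as.numeric(vaf))
  if (any(is.na(out) | out < 0 | out > 1)) {
    neo_stop("VAF must be within [0, 1] for non-fusion candidates")
  }
  out
}

#' Foreignness component and agretopicity index
#'
#' Compares mutant and wild-type binding. The agretopicity index is
#' `rank_wt / rank_mut` (large when the mutation creates binding the
#' wild-type peptide lacks). Foreignness enters the composite as the bounded
#' factor `1 - 0.5 * L(rank_wt)`: a strongly binding wild-type counterpart
#' (self-like presentation) at most halves the priority. Candidates without
#' a wild-type counterpart (frameshift, in-frame indel, fusion) are fully
#' foreign: foreignness 1, index absent.
#'
#' @param rank_mut Mutant %Rank (> 0).
#' @param rank_wt Wild-type %Rank (> 0) or `NA` when no counterpart exists.
#' @param slope,inflection Passed to [logistic_rank_weight()].
#' @return List with `foreignness` (in \[0.5, 1\]) and `agretopicity_index`
#'   (`NA` where absent).
#' @export
foreignness_component <- function(rank_mut, rank_wt, slope = 5,
                                  inflection = 2) {
  if (any(is.na(rank_mut) | rank_mut <= 0)) neo_stop("rank_mut must be > 0")
  if (any(!is.na(rank_wt) & rank_wt <= 0)) neo_stop("rank_wt must be > 0")
  has_wt <- !is.na(rank_wt)
  foreign <- rep(1, length(rank_mut))
  foreign[has_wt] <- 1 - 0.5 * logistic_rank_weight(rank_wt[has_wt],
                                                    slope, inflection)
  list(foreignness = foreign,
       agretopicity_index = ifelse(has_wt, rank_wt / rank_mut, NA_real_))
}

#' Composite priority score
#'
#' `100 * L * expression_component * clonality * foreignness`, forced to 0
#' when the candidate exactly matches the reference proteome or fails the
#' expression gate. Bounded in \[0, 100\] and strictly monotone in each
#' component on the un-vetoed domain.
#'
#' @param logistic_weight,expr_component,clonality,foreignness Component
#'   vectors in their stated ranges.
#' @param self_match Logical veto (exact proteome match).
#' @param gate_pass Logical expression-gate outcome.
#' @return Scores in \[0, 100\].
#' @export
priority_score <- function(logistic_weight, expr_component, clonality,
                           foreignness, self_match, gate_pass) {
  score <- 100 * logistic_weight * expr_component * clonality * foreignness
  score[self_match | !gate_pass] <- 0
  score
}

#' Score candidate peptides against a sample's HLA alleles
#'
#' Crosses candidate peptides with the sample's alleles, attaches %Rank
#' values (mutant and, for missense, wild-type counterpart) from a binding
#' score table, computes every component and the composite priority score.
#' Candidates lacking a prediction are dropped with a warning.
#'
#' @param peptides Candidate table from [variant_peptides()] /
#'   [fusion_peptides()].
#' @param binding `neo_binding` scores covering (peptide, allele) pairs --
#'   including wild-type counterpart peptides.
#' @param alleles Character vector of the sample's class I alleles.
#' @param gene_expr Named numeric: gene symbol -> TPM (from [gene_tpm()]).
#' @param fusion_ffpm Named numeric: `gene5::gene3` label -> FFPM.
#' @param vaf_by_variant Named numeric: variant key -> VAF.
#' @param proteome `neo_proteome` for the self-similarity veto.
#' @param config A [neo_config()] (thresholds, scales).
#' @param sample Sample label.
#' @return A `neo_scored` table with the fixed candidate-table columns, plus
#'   `variant_key` and `gate_pass` bookkeeping columns (dropped by
#'   [write_candidates_table()]).
#' @export
score_candidates <- function(peptides, binding, alleles, gene_expr,
                             fusion_ffpm = numeric(0),
                             vaf_by_variant = numeric(0),
                             proteome, config = neo_config(),
                             sample = "sample") {
  alleles <- normalize_hla(alleles)
  pd <- data.table::as.data.table(peptides)
  if (nrow(pd) == 0L) {
    out <- data.table::as.data.table(
      setNames(rep(list(character(0)), length(candidate_columns())),
               candidate_columns()))
    data.table::setattr(out, "class", c("neo_scored", class(out)))
    return(out[])
  }
  cand <- pd[rep(seq_len(nrow(pd)), each = length(alleles))]
  cand[, hla_allele := rep(alleles, times = nrow(pd))]

  bind <- data.table::as.data.table(binding)
  cand[bind, on = c(sequence = "peptide", hla_allele = "allele"),
       rank_percent := i.rank_percent]
  cand[bind, on = c(wildtype_counterpart = "peptide", hla_allele = "allele"),
       rank_percent_wt := i.rank_percent]
  n_missing <- sum(is.na(cand$rank_percent))
  if (n_missing) {
    warning(sprintf("dropped %d candidate(s) with no binding prediction",
                    n_missing), call. = FALSE)
    cand <- cand[!is.na(rank_percent)]
  }
  if (nrow(cand) == 0L) {
    return(score_candidates(empty_peptides(), binding, alleles, gene_expr,
                            fusion_ffpm, vaf_by_variant, proteome, config,
                            sample))
  }

  is_fus <- cand$source_type == "fusion"
  expr_val <- ifelse(is_fus,
                     unname(fusion_ffpm[cand$gene_label]),
                     unname(gene_expr[cand$gene_label]))
  expr_unit <- ifelse(is_fus, "FFPM", "TPM")
  gate <- expression_gate(expr_val, cand$source_type,
                          min_tpm = config$min_tpm,
                          min_ffpm = config$min_ffpm)
  if (any(is.na(expr_val))) {
    neo_log("%d candidate(s) from genes absent in abundance: gate failed",
            sum(is.na(expr_val)))
  }
  expr_comp <- ifelse(is.na(expr_val), 0,
                      expression_component(ifelse(is.na(expr_val), 0, expr_val),
                                           expr_unit,
                                           scales = config$tanh_scales))
  vaf <- ifelse(is_fus, NA_real_, unname(vaf_by_variant[cand$variant_key]))
  clon <- clonality_component(vaf, cand$source_type)
  lw <- logistic_rank_weight(cand$rank_percent, config$logistic_slope,
                             config$logistic_inflection)
  fr <- foreignness_component(cand$rank_percent, cand$rank_percent_wt,
                              config$logistic_slope,
                              config$logistic_inflection)
  selfm <- self_similarity(cand$sequence, proteome)
  score <- priority_score(lw, expr_comp, clon, fr$foreignness, selfm, gate)

  out <- data.table::data.table(
    sample = sample,
    source_type = cand$source_type,
    gene_label = cand$gene_label,
    peptide = cand$sequence,
    length = cand$length,
    hla_allele = cand$hla_allele,
    rank_percent = cand$rank_percent,
    rank_percent_wt = cand$rank_percent_wt,
    agretopicity_index = fr$agretopicity_index,
    expression_value = ifelse(is.na(expr_val), 0, expr_val),
    expression_unit = expr_unit,
    clonality = clon,
    logistic_weight = lw,
    expression_component = expr_comp,
    foreignness = fr$foreignness,
    self_match = selfm,
    binder_class = classify_binder(cand$rank_percent,
                                   strong = config$strong_rank,
                                   weak = config$weak_rank),
    priority_score = score,
    # provenance/bookkeeping columns; not part of the written table schema
    variant_key = cand$variant_key,
    gate_pass = gate
  )
  data.table::setattr(out, "class", c("neo_scored", class(out)))
  out[]
}

#' Rank scored candidates deterministically
#'
#' Descending priority score; ties broken by ascending %Rank, then
#' descending expression value, then lexicographic peptide, allele and gene
#' label -- a total order, so any permutation of the input yields the same
#' output.
#'
#' @param scored `neo_scored` table.
#' @return The same table, reordered.
#' @export
rank_candidates <- function(scored) {
  out <- data.table::as.data.table(scored)
  data.table::setorder(out, -priority_score, rank_percent, -expression_value,
                       peptide, hla_allele, gene_label, source_type)
  data.table::setattr(out, "class", c("neo_scored", class(out)))
  out[]
}
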