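# DNA-RNA concordance: distinguishes functional amplification (genomic gain
# with commensurate overexpression) from capture artifacts (depth spikes
# shared with the matched normal, or without RNA support) and from purely
# transcriptional elevation.

#' Mean depth over a gene's CDS intervals
#'
#' Arithmetic mean of per-base depth across the intervals; positions absent
#' from the sparse track count as depth 0.
#'
#' @param depth `neo_depth` track.
#' @param intervals Non-empty `GRanges` of the gene's CDS.
#' @return Mean depth (numeric scalar).
#' @export
locus_mean_depth <- function(depth, intervals) {
  stopifnot(inherits(depth, "neo_depth"))
  if (length(intervals) == 0L) neo_stop("empty interval set for locus depth")
  intervals <- GenomicRanges::reduce(intervals)
  total_bases <- sum(GenomicRanges::width(intervals))
  idt <- data.table::data.table(
    contig = as.character(GenomicRanges::seqnames(intervals)),
    start = GenomicRanges::start(intervals),
    end = GenomicRanges::end(intervals)
  )
  hit <- depth[idt, on = .(contig, pos >= start, pos <= end), nomatch = NULL,
               .(x.depth)]
  sum(hit$x.depth) / total_bases
}

concordance_labels <- c("concordant_amplification", "capture_artifact",
                        "transcriptional_only", "unremarkable")

#' Default concordance thresholds
#'
#' `r_dna`: minimum tumor locus/background depth ratio to call the locus
#' DNA-elevated. `r_somatic`: minimum tumor-over-normal ratio-of-ratios, so
#' spikes shared with the matched normal are not called somatic gains.
#' `t_abs` / `f_rel`: a gene is RNA-elevated when its TPM reaches
#' `max(t_abs, f_rel * cohort reference TPM)`. The logic is qualitative by
#' design; these numeric defaults are package choices, all configurable.
#'
#' @param r_dna,r_somatic,t_abs,f_rel Threshold values.
#' @return Named list of thresholds.
#' @export
concordance_thresholds <- function(r_dna = 3, r_somatic = 2, t_abs = 50,
                                   f_rel = 5) {
  stopifnot(r_dna > 0, r_somatic > 0, t_abs >= 0, f_rel >= 0)
  list(r_dna = r_dna, r_somatic = r_somatic, t_abs = t_abs, f_rel = f_rel)
}

#' Classify a locus for DNA-RNA amplification concordance
#'
#' Three booleans drive a total label mapping:
#' * `dna_elevated`: tumor locus/background depth ratio >= `r_dna` AND the
#'   tumor ratio exceeds the normal's by >= `r_somatic` (a spike present in
#'   the matched normal is capture bias, not gain);
#' * `shared_with_normal`: both tumor and normal locus ratios >= `r_dna`;
#' * `rna_elevated`: TPM >= `max(t_abs, f_rel * cohort_tpm_reference)`.
#'
#' Labels: DNA and RNA elevated and not shared -> `concordant_amplification`;
#' DNA elevated without RNA, or shared with normal -> `capture_artifact`;
#' RNA only -> `transcriptional_only`; otherwise `unremarkable`.
#'
#' @param evidence A `data.frame`/list with fields `gene`,
#'   `tumor_locus_depth`, `normal_locus_depth`, `tumor_background_depth`,
#'   `normal_background_depth`, `tpm`, `cohort_tpm_reference`.
#' @param thresholds A [concordance_thresholds()] list.
#' @return `data.table` with the evidence ratios, the three booleans and the
#'   `label` column.
#' @export
classify_concordance <- function(evidence,
                                 thresholds = concordance_thresholds()) {
  if (is.list(evidence) && !is.data.frame(evidence)) {
    evidence <- data.table::as.data.table(evidence)
  }
  e <- data.table::as.data.table(evidence)
  assert_cols(e, c("gene", "tumor_locus_depth", "normal_locus_depth",
                   "tumor_background_depth", "normal_background_depth",
                   "tpm", "cohort_tpm_reference"), "locus evidence")
  if (any(e$tumor_background_depth <= 0 | e$normal_background_depth <= 0)) {
    neo_stop("background depth must be > 0")
  }
  eps <- 1e-9
  tumor_ratio <- e$tumor_locus_depth / e$tumor_background_depth
  normal_ratio <- e$normal_locus_depth / e$normal_background_depth
  dna_elevated <- tumor_ratio >= thresholds$r_dna &
    tumor_ratio / pmax(normal_ratio, eps) >= thresholds$r_somatic
  shared_with_normal <- tumor_ratio >= thresholds$r_dna &
    normal_ratio >= thresholds$r_dna
  rna_cut <- pmax(thresholds$t_abs, thresholds$f_rel * e$cohort_tpm_reference)
  rna_elevated <- e$tpm >= rna_cut
  label <- data.table::fcase(
    dna_elevated & rna_elevated & !shared_with_normal,
      "concordant_amplification",
    (dna_elevated & !rna_elevated) | shared_with_normal, "capture_artifact",
    !dna_elevated & rna_elevated, "transcriptional_only",
    default = "unremarkable"
  )
  data.table::data.table(
    gene = e$gene,
    tumor_locus_depth = e$tumor_locus_depth,
    normal_locus_depth = e$normal_locus_depth,
    tumor_background_depth = e$tumor_background_depth,
    normal_background_depth = e$normal_background_depth,
    tumor_ratio = tumor_ratio, normal_ratio = normal_ratio,
    tpm = e$tpm, cohort_tpm_reference = e$cohort_tpm_reference,
    dna_elevated = dna_elevated, rna_elevated = rna_elevated,
    shared_with_normal = shared_with_normal,
    label = label
  )
}

#' Per-gene concordance report for a sample
#'
#' Assembles locus evidence from tumor/normal depth tracks, the CDS BED and
#' gene expression, then classifies each gene.
#'
#' @param tumor_depth,normal_depth `neo_depth` tracks.
#' @param cds `GRanges` with a `gene` metadata column.
#' @param gene_expr Named numeric gene TPM vector.
#' @param cohort_reference Named numeric per-gene cohort reference TPM (e.g.
#'   cohort median), or a single number applied to all genes.
#' @param thresholds A [concordance_thresholds()] list.
#' @param genes Genes to evaluate (default: all in `cds`).
#' @return Concordance `data.table` (see [classify_concordance()]).
#' @export
concordance_report <- function(tumor_depth, normal_depth, cds, gene_expr,
                               cohort_reference = 1,
                               thresholds = concordance_thresholds(),
                               genes = NULL) {
  if (is.null(cds$gene)) neo_stop("CDS intervals need a 'gene' column")
  genes <- genes %||% unique(cds$gene)
  tumor_bg <- locus_mean_depth(tumor_depth, cds)
  normal_bg <- locus_mean_depth(normal_depth, cds)
  ref_for <- function(g) {
    if (length(cohort_reference) == 1L && is.null(names(cohort_reference))) {
      return(cohort_reference)
    }
    if (g %in% names(cohort_reference)) unname(cohort_reference[g]) else 0
  }
  rows <- lapply(genes, function(g) {
    gi <- cds[cds$gene == g]
    data.table::data.table(
      gene = g,
      tumor_locus_depth = locus_mean_depth(tumor_depth, gi),
      normal_locus_depth = locus_mean_depth(normal_depth, gi),
      tumor_background_depth = tumor_bg,
      normal_background_depth = normal_bg,
      tpm = if (g %in% names(gene_expr)) unname(gene_expr[g]) else 0,
      cohort_tpm_reference = ref_for(g)
    )
  })
  ev <- data.table::rbindlist(rows)
  ev[is.na(tpm), tpm := 0]
  classify_concordance(ev, thresholds)
}
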