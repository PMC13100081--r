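# Depth tracks are sparse (contig, pos, depth) tables; positions absent from
# the track have depth 0. Callable territory is the subset of CDS bases whose
# depth reaches a threshold -- the denominator of normalized TMB.

depth_positions_at_least <- function(depth, min_depth) {
  stopifnot(inherits(depth, "neo_depth"))
  hit <- depth[depth >= min_depth]
  if (nrow(hit) == 0L) return(GenomicRanges::GRanges())
  GenomicRanges::reduce(GenomicRanges::GRanges(
    seqnames = hit$contig,
    ranges = IRanges::IRanges(start = hit$pos, width = 1L)
  ))
}

#' Compute the callable coding territory
#'
#' The callable territory is the set of CDS positions whose sequencing depth
#' reaches `min_depth` (default 10x). It is the sample-specific denominator
#' for normalized tumor mutational burden, protecting low-coverage samples
#' from TMB underestimation.
#'
#' @param depth A `neo_depth` track from [read_depth_table()].
#' @param cds `GRanges` of CDS intervals (1-based inclusive, e.g. from
#'   [read_bed()]).
#' @param min_depth Minimum depth for a base to count as callable (>= 1).
#' @return A `neo_callable` object: merged disjoint `intervals` (`GRanges`),
#'   `total_bases`, `total_megabases`, and the `min_depth` used.
#' @export
compute_callable <- function(depth, cds, min_depth = 10L) {
  if (!is_count(min_depth) || min_depth < 1) neo_stop("min_depth must be >= 1")
  if (length(cds) == 0L) neo_stop("empty CDS interval set")
  covered <- depth_positions_at_least(depth, min_depth)
  callable <- GenomicRanges::reduce(
    GenomicRanges::intersect(covered, GenomicRanges::reduce(cds),
                             ignore.strand = TRUE))
  total <- sum(GenomicRanges::width(callable))
  structure(
    list(intervals = sort(callable), total_bases = total,
         total_megabases = total / 1e6, min_depth = as.integer(min_depth)),
    class = "neo_callable"
  )
}

#' @export
print.neo_callable <- function(x, ...) {
  cat(sprintf("<neo_callable> %d interval(s), %d bases (%.6f Mb) at >= %dx\n",
              length(x$intervals), x$total_bases, x$total_megabases,
              x$min_depth))
  invisible(x)
}

in_territory <- function(chrom, pos, territory) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L))
  IRanges::overlapsAny(gr, territory$intervals, ignore.strand = TRUE)
}

# Nonsynonymous consequence classes counted in the TMB numerator. Stop-gain
# is a nonsynonymous event for burden even though it is excluded from the
# epitope path.
tmb_consequences <- c("missense", "stop_gain", "frameshift", "inframe_indel")

#' TMB eligibility of a single variant class
#'
#' A variant counts toward tumor mutational burden iff it passed all caller
#' filters (`PASS`), has tumor depth at least `min_depth`, lies inside the
#' callable territory, and is nonsynonymous (missense, stop-gain, frameshift
#' or in-frame indel). Synonymous variants never count.
#'
#' @param variants `neo_variants` table.
#' @param territory `neo_callable` from [compute_callable()].
#' @param min_depth Minimum tumor depth at the variant site.
#' @return Logical vector along `variants`.
#' @export
is_tmb_eligible <- function(variants, territory, min_depth = 10L) {
  if (nrow(variants) == 0L) return(logical(0))
  variants$filter == "PASS" &
    variants$tumor_depth >= min_depth &
    variants$consequence %in% tmb_consequences &
    in_territory(variants$chrom, variants$pos, territory)
}

#' Breadth of coverage over a target
#'
#' Fraction of target bases reaching at least `min_depth`.
#'
#' @inheritParams compute_callable
#' @param target `GRanges` of target intervals.
#' @return Fraction in \[0, 1\].
#' @export
breadth_of_coverage <- function(depth, target, min_depth = 10L) {
  if (length(target) == 0L) neo_stop("empty target interval set")
  target <- GenomicRanges::reduce(target)
  covered <- GenomicRanges::intersect(
    depth_positions_at_least(depth, min_depth), target, ignore.strand = TRUE)
  sum(GenomicRanges::width(covered)) / sum(GenomicRanges::width(target))
}

#' Callable-territory-normalized tumor mutational burden
#'
#' TMB is the count of eligible nonsynonymous mutations divided by the
#' callable territory in megabases (see [is_tmb_eligible()]). The report also
#' carries the Ti/Tv ratio over the same PASS/depth-qualified variants (see
#' [titv_ratio()]) and breadth of coverage at the callable threshold.
#'
#' @param variants `neo_variants` table.
#' @param territory `neo_callable`; its `total_bases` must be positive.
#' @param depth Optional `neo_depth` track (for breadth); `NULL` skips it.
#' @param cds Optional full CDS `GRanges` (breadth denominator).
#' @param min_depth Minimum tumor depth at the variant site.
#' @return A `neo_tmb` object: `nonsyn_count`, `callable_mb`, `tmb`, `titv`
#'   (`NA` when undefined), `breadth_at_threshold` (`NA` when depth/cds not
#'   given).
#' @export
compute_tmb <- function(variants, territory, depth = NULL, cds = NULL,
                        min_depth = 10L) {
  stopifnot(inherits(territory, "neo_callable"))
  if (territory$total_bases <= 0) {
    neo_stop("callable territory is empty; sample unusable for TMB",
             class = "neo_stage_error")
  }
  eligible <- is_tmb_eligible(variants, territory, min_depth)
  n <- sum(eligible)
  breadth <- if (!is.null(depth) && !is.null(cds)) {
    breadth_of_coverage(depth, cds, territory$min_depth)
  } else NA_real_
  structure(
    list(nonsyn_count = n,
         callable_mb = territory$total_megabases,
         tmb = n / territory$total_megabases,
         titv = titv_ratio(variants, regions = territory$intervals,
                           min_depth = min_depth),
         breadth_at_threshold = breadth),
    class = "neo_tmb"
  )
}

#' @export
print.neo_tmb <- function(x, ...) {
  cat(sprintf(
    "<neo_tmb> %d nonsynonymous / %.6f Mb callable = %.3f mut/Mb; Ti/Tv %s\n",
    x$nonsyn_count, x$callable_mb, x$tmb,
    if (is.na(x$titv)) "undefined" else sprintf("%.3f", x$titv)))
  invisible(x)
}

#' Write a one-row TMB summary table
#' @param report `neo_tmb` object.
#' @param path Output path.
#' @param sample Sample label for the first column.
#' @export
write_tmb_report <- function(report, path, sample = "sample") {
  dt <- data.table::data.table(
    sample = sample,
    nonsyn_count = report$nonsyn_count,
    callable_mb = report$callable_mb,
    tmb = report$tmb,
    titv = report$titv,
    breadth_at_threshold = report$breadth_at_threshold
  )
  write_tsv_deterministic(dt, path,
                          num_cols = c("callable_mb", "tmb", "titv",
                                       "breadth_at_threshold"))
}

is_transition <- function(ref, alt) {
  (ref == "A" & alt == "G") | (ref == "G" & alt == "A") |
    (ref == "C" & alt == "T") | (ref == "T" & alt == "C")
}

#' Transition/transversion ratio
#'
#' Computed over PASS, depth-qualified, biallelic SNVs restricted to the
#' given regions. Transitions are A<->G and C<->T; everything else among
#' single-base substitutions is a transversion. With zero transversions the
#' ratio is undefined and reported as `NA` (not infinity).
#'
#' @param variants `neo_variants` table.
#' @param regions `GRanges` restriction (e.g. capture targets); `NULL` means
#'   no restriction.
#' @param min_depth Minimum tumor depth.
#' @return Ti/Tv ratio, or `NA_real_` when undefined.
#' @export
titv_ratio <- function(variants, regions = NULL, min_depth = 10L) {
  if (nrow(variants) == 0L) return(NA_real_)
  snv <- variants$filter == "PASS" &
    variants$tumor_depth >= min_depth &
    nchar(variants$ref) == 1L & nchar(variants$alt) == 1L &
    variants$ref %in% c("A", "C", "G", "T") &
    variants$alt %in% c("A", "C", "G", "T") &
    variants$ref != variants$alt
  if (!is.null(regions)) {
    gr <- GenomicRanges::GRanges(variants$chrom,
                                 IRanges::IRanges(variants$pos, width = 1L))
    snv <- snv & IRanges::overlapsAny(gr, regions, ignore.strand = TRUE)
  }
  ref <- variants$ref[snv]; alt <- variants$alt[snv]
  ti <- sum(is_transition(ref, alt))
  tv <- sum(snv) - ti
  if (tv == 0L) NA_real_ else ti / tv
}
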