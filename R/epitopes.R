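# Mutant protein contexts and 8-11-mer candidate enumeration.
#
# A context records the mutant protein sequence and the 1-based span of
# residues that differ from reference. Two span types exist: "residues"
# (windows must cover at least one altered residue) and "joint" (in-frame
# deletions: no altered residue exists, so windows must straddle the newly
# adjacent residue pair j, j+1).

new_context <- function(mutant_sequence, span_start, span_end,
                        span_type = c("residues", "joint"),
                        wildtype_sequence = NA_character_,
                        source_type, gene_label, variant_key) {
  span_type <- match.arg(span_type)
  structure(
    list(mutant_sequence = mutant_sequence,
         span_start = span_start, span_end = span_end,
         span_type = span_type,
         wildtype_sequence = wildtype_sequence,
         source_type = source_type,
         gene_label = gene_label,
         variant_key = variant_key),
    class = "neo_context"
  )
}

#' @export
print.neo_context <- function(x, ...) {
  cat(sprintf("<neo_context> %s %s: %d aa, altered %s %d..%d\n",
              x$source_type, x$gene_label, nchar(x$mutant_sequence),
              x$span_type, x$span_start, x$span_end))
  invisible(x)
}

variant_key <- function(v) {
  paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
}

#' Select variants eligible for epitope generation
#'
#' The epitope path keeps PASS variants with tumor depth at least
#' `min_depth` whose consequence is missense, in-frame indel or frameshift.
#' Synonymous variants and stop-gains are dropped: stop-gains truncate the
#' protein (and are prone to nonsense-mediated decay) and do not produce the
#' substitution/indel peptide context modeled here, although they still count
#' toward TMB (see [is_tmb_eligible()]).
#'
#' @param variants `neo_variants` table.
#' @param min_depth Minimum tumor depth at the variant site.
#' @return The eligible subset, same class.
#' @export
select_epitope_variants <- function(variants, min_depth = 10L) {
  keep <- variants$filter == "PASS" &
    variants$tumor_depth >= min_depth &
    variants$consequence %in% c("missense", "inframe_indel", "frameshift")
  variants[keep]
}

#' Build the mutant protein context for a missense variant
#'
#' @param v One-row `neo_variants` record with protein-level annotation
#'   (`transcript_id`, `protein_position`, `ref_aa`, `alt_aa`).
#' @param proteins Named character vector: transcript id -> protein sequence.
#' @return A `neo_context` (span = the substituted residue), or an error if
#'   the annotated reference residue does not match the protein sequence.
#' @export
build_missense_context <- function(v, proteins) {
  v <- as.list(v)
  seq <- proteins[[v$transcript_id]] %||%
    neo_stop(sprintf("no protein sequence for transcript %s", v$transcript_id))
  p <- as.integer(v$protein_position)
  if (is.na(p) || p < 1L || p > nchar(seq)) {
    neo_stop(sprintf("protein_position %s outside protein for %s",
                     v$protein_position, v$transcript_id))
  }
  found <- substr(seq, p, p + nchar(v$ref_aa) - 1L)
  if (!identical(found, v$ref_aa)) {
    neo_stop(sprintf(
      "annotation out of sync: protein %s position %d is '%s', annotation says '%s'",
      v$transcript_id, p, found, v$ref_aa))
  }
  mutant <- paste0(substr(seq, 1L, p - 1L), v$alt_aa,
                   substr(seq, p + 1L, nchar(seq)))
  new_context(mutant, p, p, "residues", wildtype_sequence = seq,
              source_type = "snv", gene_label = v$gene_symbol,
              variant_key = variant_key(v))
}

apply_cds_edit <- function(cds, pos, ref, alt) {
  pos <- as.integer(pos)
  if (is.na(pos) || pos < 1L || pos + nchar(ref) - 1L > nchar(cds)) {
    neo_stop("cds_position outside CDS")
  }
  found <- substr(cds, pos, pos + nchar(ref) - 1L)
  if (!identical(found, ref)) {
    neo_stop(sprintf(
      "annotation out of sync: CDS at %d is '%s', annotation says '%s'",
      pos, found, ref))
  }
  paste0(substr(cds, 1L, pos - 1L), alt,
         substr(cds, pos + nchar(ref), nchar(cds)))
}

common_prefix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- strsplit(substr(a, 1, n), "")[[1]]
  bv <- strsplit(substr(b, 1, n), "")[[1]]
  d <- which(av != bv)
  if (length(d)) d[1L] - 1L else n
}

#' Build the mutant protein context for a frameshift indel
#'
#' The indel is applied to the transcript CDS, the mutant CDS is translated
#' from codon 1 in the shifted frame, and the altered span runs from the
#' first residue that differs from the reference translation through the new
#' terminus (the stop itself is excluded). A frameshift whose shifted frame
#' stops immediately yields no context (`NULL`).
#'
#' @param v One-row `neo_variants` record with CDS-level annotation
#'   (`transcript_id`, `cds_position`, `cds_ref`, `cds_alt`).
#' @param cds_sequences Named character vector: transcript id -> CDS.
#' @return A `neo_context`, or `NULL` for the degenerate empty-tail case.
#' @export
build_frameshift_context <- function(v, cds_sequences) {
  v <- as.list(v)
  cds <- cds_sequences[[v$transcript_id]] %||%
    neo_stop(sprintf("no CDS for transcript %s", v$transcript_id))
  shift <- abs(nchar(v$cds_alt) - nchar(v$cds_ref)) %% 3L
  if (shift == 0L) {
    neo_stop("in-frame indel routed to build_frameshift_context; use build_inframe_context")
  }
  mut_cds <- apply_cds_edit(cds, v$cds_position, v$cds_ref, v$cds_alt)
  ref_aa <- translate_cds(cds)
  mut_aa <- translate_cds(mut_cds)
  d <- common_prefix_len(ref_aa, mut_aa) + 1L
  if (d > nchar(mut_aa)) {
    neo_log("frameshift %s yields no novel residues; skipped", variant_key(v))
    return(NULL)
  }
  new_context(mut_aa, d, nchar(mut_aa), "residues",
              source_type = "frameshift", gene_label = v$gene_symbol,
              variant_key = variant_key(v))
}

#' Build the mutant protein context for an in-frame indel
#'
#' Insertions mark the inserted residues as the altered span; deletions leave
#' no altered residue, so the span becomes the deletion joint (the newly
#' adjacent residue pair), which candidate windows must straddle.
#'
#' @inheritParams build_frameshift_context
#' @return A `neo_context`, or `NULL` when a terminal deletion leaves no
#'   joint to span.
#' @export
build_inframe_context <- function(v, cds_sequences) {
  v <- as.list(v)
  cds <- cds_sequences[[v$transcript_id]] %||%
    neo_stop(sprintf("no CDS for transcript %s", v$transcript_id))
  if (abs(nchar(v$cds_alt) - nchar(v$cds_ref)) %% 3L != 0L) {
    neo_stop("frameshift indel routed to build_inframe_context; use build_frameshift_context")
  }
  mut_cds <- apply_cds_edit(cds, v$cds_position, v$cds_ref, v$cds_alt)
  ref_aa <- translate_cds(cds)
  mut_aa <- translate_cds(mut_cds)
  if (identical(ref_aa, mut_aa)) return(NULL)  # silent at protein level
  p <- common_prefix_len(ref_aa, mut_aa)
  # longest common suffix of the parts beyond the shared prefix
  rev1 <- function(x) paste(rev(strsplit(x, "")[[1]]), collapse = "")
  s <- common_prefix_len(rev1(substr(ref_aa, p + 1L, nchar(ref_aa))),
                         rev1(substr(mut_aa, p + 1L, nchar(mut_aa))))
  span_start <- p + 1L
  span_end <- nchar(mut_aa) - s
  if (span_end >= span_start) {
    new_context(mut_aa, span_start, span_end, "residues",
                wildtype_sequence = ref_aa,
                source_type = "inframe_indel", gene_label = v$gene_symbol,
                variant_key = variant_key(v))
  } else {
    # pure deletion: windows must straddle the joint between p and p+1
    if (p < 1L || p + 1L > nchar(mut_aa)) return(NULL)
    new_context(mut_aa, p, p, "joint",
                wildtype_sequence = ref_aa,
                source_type = "inframe_indel", gene_label = v$gene_symbol,
                variant_key = variant_key(v))
  }
}

peptide_ok <- function(x) !grepl("[X*]", x)

empty_peptides <- function() {
  data.table::data.table(
    sequence = character(0), source_type = character(0),
    gene_label = character(0), variant_key = character(0),
    window_start = integer(0), length = integer(0),
    covers = character(0), wildtype_counterpart = character(0)
  )
}

# Shared sliding-window core: all windows of the requested lengths within
# [1, n] whose [s, e] satisfies s <= smax and e >= emin.
window_grid <- function(n, lengths, smax, emin) {
  out <- vector("list", length(lengths))
  for (k in seq_along(lengths)) {
    L <- lengths[k]
    lo <- max(1L, emin - L + 1L)
    hi <- min(smax, n - L + 1L)
    if (hi >= lo) out[[k]] <- data.table::data.table(
      window_start = seq.int(lo, hi), length = L)
  }
  data.table::rbindlist(out)
}

#' Enumerate 8-11-mer candidate peptides from a mutant context
#'
#' Emits every window of each requested length that covers at least one
#' altered residue (or, for deletion joints, straddles the newly adjacent
#' pair), truncated only by the sequence termini. Peptides containing `X` or
#' a stop are suppressed; duplicate sequences from different windows of the
#' same context keep the first window (lengths ascending, then start).
#' Missense candidates carry the same-coordinate wild-type peptide.
#'
#' @param ctx A `neo_context`, or `NULL` (yields an empty table).
#' @param lengths Integer vector of window lengths within 8..11.
#' @return `data.table` with columns `sequence, source_type, gene_label,
#'   variant_key, window_start, length, covers, wildtype_counterpart`.
#' @export
enumerate_peptides <- function(ctx, lengths = 8:11) {
  stopifnot(all(lengths >= 8L & lengths <= 11L))
  if (is.null(ctx)) return(empty_peptides())
  stopifnot(inherits(ctx, "neo_context"))
  n <- nchar(ctx$mutant_sequence)
  grid <- if (ctx$span_type == "joint") {
    window_grid(n, lengths, smax = ctx$span_start, emin = ctx$span_start + 1L)
  } else {
    window_grid(n, lengths, smax = ctx$span_end, emin = ctx$span_start)
  }
  if (nrow(grid) == 0L) return(empty_peptides())
  data.table::setorder(grid, length, window_start)
  wend <- grid$window_start + grid$length - 1L
  seqs <- substring(ctx$mutant_sequence, grid$window_start, wend)
  covers <- if (ctx$span_type == "joint") {
    sprintf("%d-%d", ctx$span_start, ctx$span_start + 1L)
  } else {
    sprintf("%d-%d", pmax(grid$window_start, ctx$span_start),
            pmin(wend, ctx$span_end))
  }
  wt <- if (!is.na(ctx$wildtype_sequence) && ctx$source_type == "snv") {
    substring(ctx$wildtype_sequence, grid$window_start, wend)
  } else NA_character_
  out <- data.table::data.table(
    sequence = seqs, source_type = ctx$source_type,
    gene_label = ctx$gene_label, variant_key = ctx$variant_key,
    window_start = grid$window_start, length = grid$length,
    covers = covers, wildtype_counterpart = wt
  )
  out <- out[peptide_ok(sequence)]
  out[!duplicated(sequence)]
}

#' Enumerate junction-spanning peptides for an in-frame fusion
#'
#' The chimeric junction CDS is translated from its first codon (the
#' sequence is supplied in the fusion ORF's frame; `junction_offset` locates
#' the breakpoint within it). Only windows containing at least one residue
#' with 5'-partner content and one with 3'-partner content are kept -- every
#' emitted peptide straddles the breakpoint and is therefore strictly
#' non-self. A stop codon upstream of the junction yields no peptides.
#'
#' @param f One-row `neo_fusions` record (must carry `junction_cds` and
#'   `junction_offset`).
#' @param lengths Integer vector of window lengths within 8..11.
#' @return Candidate peptide `data.table` (see [enumerate_peptides()]).
#' @export
fusion_peptides <- function(f, lengths = 8:11) {
  stopifnot(all(lengths >= 8L & lengths <= 11L))
  f <- as.list(f)
  if (is.na(f$junction_cds) || is.na(f$junction_offset)) {
    neo_stop(sprintf("fusion %s::%s has no junction sequence/offset",
                     f$gene5, f$gene3))
  }
  off <- as.integer(f$junction_offset)
  if (off < 0L || off > nchar(f$junction_cds)) {
    neo_stop("junction_offset inconsistent with junction sequence length")
  }
  aa <- translate_cds(f$junction_cds)
  m <- nchar(aa)
  gene_label <- paste0(f$gene5, "::", f$gene3)
  key <- paste(gene_label, f$breakpoint5 %||% "?", f$breakpoint3 %||% "?",
               sep = ":")
  n5 <- ceiling(off / 3)        # residues 1..n5 carry 5'-partner bases
  f3 <- off %/% 3L + 1L         # residues f3..m carry 3'-partner bases
  if (n5 < 1L || f3 > m) return(empty_peptides())  # stop before junction, or
                                                   # one-sided sequence
  grid <- window_grid(m, lengths, smax = n5, emin = f3)
  if (nrow(grid) == 0L) return(empty_peptides())
  data.table::setorder(grid, length, window_start)
  wend <- grid$window_start + grid$length - 1L
  out <- data.table::data.table(
    sequence = substring(aa, grid$window_start, wend),
    source_type = "fusion", gene_label = gene_label, variant_key = key,
    window_start = grid$window_start, length = grid$length,
    covers = sprintf("%d-%d", min(f3, n5), max(f3, n5)),
    wildtype_counterpart = NA_character_
  )
  out <- out[peptide_ok(sequence)]
  out[!duplicated(sequence)]
}

#' Build contexts and peptides for a set of eligible variants
#'
#' Routes each variant to its context builder by consequence class and pools
#' the enumerated candidates. Variants whose annotation cannot be resolved
#' (missing sequence, mismatched reference residue/base) raise errors unless
#' `on_error = "skip"`, which logs and drops them.
#'
#' @param variants Eligible `neo_variants` (see [select_epitope_variants()]).
#' @param proteins Named protein sequences (by transcript id).
#' @param cds_sequences Named CDS sequences (by transcript id).
#' @param lengths Window lengths, within 8..11.
#' @param on_error `"stop"` or `"skip"`.
#' @return Pooled candidate `data.table`; identical sequences arising from
#'   different variants remain distinct records.
#' @export
variant_peptides <- function(variants, proteins, cds_sequences,
                             lengths = 8:11, on_error = c("stop", "skip")) {
  on_error <- match.arg(on_error)
  res <- vector("list", nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i]
    build <- switch(v$consequence,
      missense = function() build_missense_context(v, proteins),
      frameshift = function() build_frameshift_context(v, cds_sequences),
      inframe_indel = function() build_inframe_context(v, cds_sequences),
      neo_stop(sprintf("consequence '%s' has no epitope path", v$consequence))
    )
    ctx <- if (on_error == "skip") {
      tryCatch(build(), neo_error = function(e) {
        neo_log("skipping %s: %s", variant_key(v), conditionMessage(e))
        NULL
      })
    } else build()
    res[[i]] <- enumerate_peptides(ctx, lengths)
  }
  out <- data.table::rbindlist(res)
  if (nrow(out) == 0L) empty_peptides() else out
}
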