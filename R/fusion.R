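#' Fusion filter configuration
#'
#' Defaults mirror standard high-stringency post-filtering of Arriba calls:
#' at least 5 junction (split-read) reads and/or discordant pairs, caller
#' confidence `high`, and an in-frame chimeric reading frame (a plausible ORF
#' is required for peptide generation). Blacklisting is the upstream caller's
#' job and is not re-applied here.
#'
#' @param min_junction_support Minimum support count; the record is kept if
#'   either junction reads or discordant pairs reach it.
#' @param required_confidence Confidence classes accepted.
#' @param require_in_frame Keep only in-frame fusions.
#' @return A `fusion_filter_config` list.
#' @export
fusion_filter_config <- function(min_junction_support = 5L,
                                 required_confidence = "high",
                                 require_in_frame = TRUE) {
  if (!is_count(min_junction_support)) {
    neo_stop("min_junction_support must be a non-negative integer")
  }
  structure(list(min_junction_support = as.integer(min_junction_support),
                 required_confidence = required_confidence,
                 require_in_frame = isTRUE(require_in_frame)),
            class = "fusion_filter_config")
}

#' Filter fusion records for the epitope path
#'
#' @param fusions `neo_fusions` table from [read_fusion_table()].
#' @param cfg A [fusion_filter_config()].
#' @return The retained subset, same class.
#' @export
filter_fusions <- function(fusions, cfg = fusion_filter_config()) {
  stopifnot(inherits(fusions, "neo_fusions"))
  keep <- (fusions$junction_reads >= cfg$min_junction_support |
             fusions$discordant_pairs >= cfg$min_junction_support) &
    fusions$confidence %in% cfg$required_confidence
  if (cfg$require_in_frame) keep <- keep & fusions$frame_status == "in_frame"
  fusions[keep]
}

#' Fusion fragments per million mapped reads (FFPM)
#'
#' Fusion-specific support reads normalized by total mapped library depth:
#' `support / total_mapped * 1e6`. By default support is junction reads plus
#' discordant pairs; set `mode = "junction"` to count split reads only.
#'
#' @param fusions `neo_fusions` table (or use `support_reads` directly).
#' @param total_mapped_reads Total mapped reads in the RNA library (> 0).
#' @param mode `"junction_plus_discordant"` (default) or `"junction"`.
#' @param support_reads Optional numeric vector of support counts, bypassing
#'   `fusions`.
#' @return Numeric FFPM vector.
#' @export
compute_ffpm <- function(fusions = NULL, total_mapped_reads,
                         mode = c("junction_plus_discordant", "junction"),
                         support_reads = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(total_mapped_reads) || total_mapped_reads <= 0) {
    neo_stop("total_mapped_reads must be > 0")
  }
  if (is.null(support_reads)) {
    stopifnot(inherits(fusions, "neo_fusions"))
    support_reads <- fusions$junction_reads +
      if (mode == "junction_plus_discordant") fusions$discordant_pairs else 0L
  }
  support_reads / total_mapped_reads * 1e6
}
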