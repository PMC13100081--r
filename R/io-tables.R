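#' Read a BED file of CDS intervals
#'
#' BED is 0-based half-open; the returned [GenomicRanges::GRanges] is 1-based
#' inclusive (so `chr1 10 20` covers positions 11..20). A 4th column, when
#' present, is kept as the `gene` metadata column.
#'
#' @param path BED file (3+ columns, tab- or space-separated).
#' @return `GRanges` of 1-based inclusive intervals.
#' @export
read_bed <- function(path) {
  assert_file(path, "BED")
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1L))
  if (ncol(dt) < 3L) neo_stop("BED file must have >= 3 columns")
  start0 <- suppressWarnings(as.numeric(dt[[2L]]))
  end0 <- suppressWarnings(as.numeric(dt[[3L]]))
  bad <- which(is.na(start0) | is.na(end0) | end0 <= start0)
  if (length(bad)) {
    neo_stop(sprintf("BED coordinate violation (end <= start or non-numeric) at line %d",
                     bad[1L]))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = dt[[1L]],
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0)
  )
  if (ncol(dt) >= 4L) gr$gene <- as.character(dt[[4L]])
  gr
}

#' Write 1-based inclusive intervals back to BED (0-based half-open)
#' @param gr `GRanges`, optionally with a `gene` metadata column.
#' @param path Output path.
#' @export
write_bed <- function(gr, path) {
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
  if (!is.null(gr$gene)) dt[, name := gr$gene]
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, eol = "\n")
  invisible(path)
}

#' Read a per-base depth table
#'
#' Three tab-separated columns in the samtools-depth dialect: contig, 1-based
#' position, integer depth. The track may be sparse; positions absent from the
#' file count as depth 0 everywhere downstream.
#'
#' @param path Depth table path.
#' @return A keyed `data.table` (`contig`, `pos`, `depth`) of class
#'   `neo_depth`.
#' @export
read_depth_table <- function(path) {
  assert_file(path, "depth table")
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("contig", "pos", "depth"),
                          colClasses = list(character = 1L))
  pos <- suppressWarnings(as.integer(dt[["pos"]]))
  depth <- suppressWarnings(as.integer(dt[["depth"]]))
  bad <- which(is.na(pos) | is.na(depth) | depth < 0 | pos < 1)
  if (length(bad)) {
    neo_stop(sprintf("malformed depth record at line %d: '%s'",
                     bad[1L], paste(unlist(dt[bad[1L]]), collapse = "\t")))
  }
  out <- data.table::data.table(contig = as.character(dt[["contig"]]),
                                pos = pos, depth = depth)
  data.table::setkeyv(out, c("contig", "pos"))
  data.table::setattr(out, "class", c("neo_depth", class(out)))
  out[]
}

#' Normalize HLA class I allele names
#'
#' Accepts `A*24:02`, `HLA-A*24:02`, `hla-b*58:01` etc. and returns the
#' canonical 4-digit form `HLA-A*24:02`.
#'
#' @param x Character vector of allele names.
#' @return Character vector of normalized alleles.
#' @export
normalize_hla <- function(x) {
  x <- toupper(trimws(x))
  x <- sub("^HLA-", "", x)
  m <- regmatches(x, regexec("^([ABC])\\*?([0-9]{2,3}):([0-9]{2,3})", x))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad)) {
    neo_stop(sprintf("unrecognized HLA class I allele(s): %s",
                     paste(unique(x[bad]), collapse = ", ")))
  }
  vapply(m, function(g) sprintf("HLA-%s*%s:%s", g[2L], g[3L], g[4L]), "")
}

#' Read an HLA allele list (one allele per line)
#' @param path Text file, one class I allele per line; `#` comments allowed.
#' @return Character vector of normalized `HLA-[ABC]*NN:NN` alleles.
#' @export
read_hla_list <- function(path) {
  assert_file(path, "HLA list")
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  unique(normalize_hla(lines))
}

#' Read a transcript abundance table (Kallisto dialect)
#'
#' Expects columns `target_id` and `tpm`; an optional `gene` column (or a
#' separate `tx2gene` two-column table) maps transcripts to gene symbols.
#'
#' @param path Abundance table path (tab-separated).
#' @param tx2gene Optional `data.frame`/`data.table` with columns
#'   `target_id`, `gene`.
#' @return A `neo_abundance` object: list with named numeric `tpm` and named
#'   character `gene` (both keyed by transcript id).
#' @export
read_abundance <- function(path, tx2gene = NULL) {
  assert_file(path, "abundance table")
  dt <- data.table::fread(path, sep = "\t")
  assert_cols(dt, c("target_id", "tpm"), "abundance table")
  tpm <- as.numeric(dt$tpm)
  if (anyNA(tpm) || any(tpm < 0)) neo_stop("abundance table has missing or negative TPM")
  tpm <- setNames(tpm, as.character(dt$target_id))
  gene <- if ("gene" %in% names(dt)) {
    setNames(as.character(dt$gene), names(tpm))
  } else if (!is.null(tx2gene)) {
    t2g <- data.table::as.data.table(tx2gene)
    assert_cols(t2g, c("target_id", "gene"), "tx2gene table")
    setNames(as.character(t2g$gene)[match(names(tpm), t2g$target_id)],
             names(tpm))
  } else {
    setNames(rep(NA_character_, length(tpm)), names(tpm))
  }
  structure(list(tpm = tpm, gene = gene), class = "neo_abundance")
}

#' Aggregate transcript TPM to gene level
#'
#' Gene-level abundance is the plain sum of the gene's transcript TPMs, which
#' conserves total TPM. Transcripts with no gene mapping are reported under
#' their own transcript id (with a warning).
#'
#' @param abundance A `neo_abundance` from [read_abundance()].
#' @return Named numeric vector: gene symbol -> TPM.
#' @export
gene_tpm <- function(abundance) {
  stopifnot(inherits(abundance, "neo_abundance"))
  if (!length(abundance$tpm)) return(setNames(numeric(0), character(0)))
  gene <- abundance$gene
  orphan <- is.na(gene) | !nzchar(gene)
  if (any(orphan)) {
    warning(sprintf("%d transcript(s) with no gene mapping reported under their own id",
                    sum(orphan)), call. = FALSE)
    gene[orphan] <- names(abundance$tpm)[orphan]
  }
  out <- tapply(abundance$tpm, gene, sum)
  setNames(as.numeric(out), names(out))
}

# Arriba output dialect: these columns must be present.
.arriba_required <- c("gene1", "gene2", "breakpoint1", "breakpoint2",
                      "split_reads1", "split_reads2", "discordant_mates",
                      "confidence", "reading_frame")

#' Read a fusion call table (Arriba dialect)
#'
#' One record per row. Junction support is the sum of the two split-read
#' columns. The chimeric coding sequence around the junction and the number of
#' its bases contributed by the 5' partner are taken from the
#' `transcript_sequence` column when it carries a `|` breakpoint marker
#' (Arriba's convention), otherwise from a sidecar FASTA whose records are
#' named `gene5::gene3` with an `offset=<n>` token in the header.
#'
#' @param path Tab-separated fusion table; a leading `#` on the header line is
#'   tolerated.
#' @param junction_fasta Optional sidecar FASTA supplying junction sequences
#'   for callers that omit them.
#' @return A `data.table` of class `neo_fusions` with columns `gene5`,
#'   `gene3`, `breakpoint5`, `breakpoint3`, `junction_reads`,
#'   `discordant_pairs`, `confidence`, `frame_status`, `junction_cds`,
#'   `junction_offset`.
#' @export
read_fusion_table <- function(path, junction_fasta = NULL) {
  assert_file(path, "fusion table")
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  names(dt) <- sub("^#", "", names(dt))
  assert_cols(dt, .arriba_required, "fusion table")

  frame <- tolower(as.character(dt$reading_frame))
  frame_status <- data.table::fcase(
    frame %chin% c("in-frame", "in_frame", "inframe"), "in_frame",
    frame %chin% c("out-of-frame", "out_of_frame", "stop-codon", "stop_codon"),
      "out_of_frame",
    default = "unknown"
  )

  out <- data.table::data.table(
    gene5 = as.character(dt$gene1),
    gene3 = as.character(dt$gene2),
    breakpoint5 = as.character(dt$breakpoint1),
    breakpoint3 = as.character(dt$breakpoint2),
    junction_reads = as.integer(dt$split_reads1) + as.integer(dt$split_reads2),
    discordant_pairs = as.integer(dt$discordant_mates),
    confidence = tolower(as.character(dt$confidence)),
    frame_status = frame_status,
    junction_cds = NA_character_,
    junction_offset = NA_integer_
  )
  if (any(out$junction_reads < 0 | out$discordant_pairs < 0, na.rm = TRUE)) {
    neo_stop("fusion table has negative read support")
  }

  if ("transcript_sequence" %in% names(dt)) {
    ts <- toupper(as.character(dt$transcript_sequence))
    has_mark <- !is.na(ts) & grepl("|", ts, fixed = TRUE)
    out$junction_offset[has_mark] <-
      as.integer(regexpr("|", ts[has_mark], fixed = TRUE)) - 1L
    out$junction_cds[has_mark] <- gsub("|", "", ts[has_mark], fixed = TRUE)
  }
  if (!is.null(junction_fasta)) {
    sidecar <- read_fasta(junction_fasta)
    hdrs <- names(sidecar)
    # full headers needed for the offset token
    full <- names(Biostrings::readBStringSet(junction_fasta))
    key <- sub("\\s.*$", "", full)
    off <- suppressWarnings(as.integer(sub(".*offset=([0-9]+).*", "\\1", full)))
    idx <- match(paste0(out$gene5, "::", out$gene3), key)
    fill <- is.na(out$junction_cds) & !is.na(idx)
    out$junction_cds[fill] <- unname(sidecar[idx[fill]])
    out$junction_offset[fill] <- off[idx[fill]]
  }
  bad_off <- !is.na(out$junction_offset) &
    (out$junction_offset < 0L | out$junction_offset > nchar(out$junction_cds))
  if (any(bad_off)) {
    neo_stop(sprintf("junction_offset outside junction sequence for %s",
                     paste0(out$gene5[bad_off], "::", out$gene3[bad_off])[1L]))
  }
  data.table::setattr(out, "class", c("neo_fusions", class(out)))
  out[]
}

# Columns of the ranked candidates table, in their fixed output order.
candidate_columns <- function() {
  c("sample", "source_type", "gene_label", "peptide", "length", "hla_allele",
    "rank_percent", "rank_percent_wt", "agretopicity_index",
    "expression_value", "expression_unit", "clonality", "logistic_weight",
    "expression_component", "foreignness", "self_match", "binder_class",
    "priority_score")
}

#' Write the ranked candidates table
#'
#' Fixed column order, deterministic row order (the order produced by
#' [rank_candidates()]), and fixed-precision floats, so identical inputs yield
#' byte-identical files.
#'
#' @param candidates Scored candidate table (from [score_candidates()] /
#'   [rank_candidates()]); an empty table writes a header-only file.
#' @param path Output path.
#' @export
write_candidates_table <- function(candidates, path) {
  cols <- candidate_columns()
  dt <- data.table::as.data.table(candidates)
  if (nrow(dt) == 0L) {
    dt <- data.table::as.data.table(
      setNames(rep(list(character(0)), length(cols)), cols))
  }
  assert_cols(dt, cols, "candidates table")
  write_tsv_deterministic(
    dt[, cols, with = FALSE], path,
    num_cols = c("rank_percent", "rank_percent_wt", "agretopicity_index",
                 "expression_value", "clonality", "logistic_weight",
                 "expression_component", "foreignness", "priority_score"))
}
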