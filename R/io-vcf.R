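consequence_levels <- c("missense", "synonymous", "stop_gain",
                        "inframe_indel", "frameshift", "other")

# Map VEP consequence terms (possibly '&'-joined) onto the engine's classes.
map_vep_consequence <- function(term) {
  first <- vapply(strsplit(term %||% "", "&"), function(x) x[1] %||% "", "")
  data.table::fcase(
    grepl("missense_variant", term), "missense",
    grepl("synonymous_variant", term), "synonymous",
    grepl("stop_gained", term), "stop_gain",
    grepl("frameshift_variant", term), "frameshift",
    grepl("inframe_(insertion|deletion)", term), "inframe_indel",
    rep(TRUE, length(first)), "other"
  )
}

.effect_cols <- c("gene_symbol", "transcript_id", "consequence",
                  "protein_position", "ref_aa", "alt_aa",
                  "cds_position", "cds_ref", "cds_alt")

#' Read a tumor-normal somatic VCF into the canonical variant table
#'
#' Parses a filtered somatic VCF (VariantAnnotation-backed), splits
#' multi-allelic records per ALT allele, and attaches effect annotation from
#' either a companion tab-separated effect table (keyed on
#' chrom/pos/ref/alt) or an embedded VEP-style CSQ INFO field. Tumor depth is
#' the tumor sample's DP (or the sum of its allelic depths when DP is
#' absent); VAF is the ALT allelic depth over total allelic depth.
#'
#' @param path VCF 4.x file.
#' @param effect_source Either the path to a companion effect table with
#'   columns `chrom, pos, ref, alt` plus the effect fields
#'   (`gene_symbol, transcript_id, consequence_class, protein_position,
#'   ref_aa, alt_aa, cds_position, cds_ref, cds_alt`), or the name of a
#'   VEP-style INFO key (e.g. `"CSQ"`). Variants without annotation get
#'   consequence `other`.
#' @param tumor_sample Tumor sample column name; defaults to the last sample
#'   in the VCF. A name not present in the VCF is a hard error.
#' @return A `data.table` of class `neo_variants`: one row per ALT allele
#'   with columns `chrom, pos, ref, alt, filter, tumor_depth, vaf` and the
#'   effect fields. `filter` is the `;`-joined FILTER string (`PASS` or
#'   labels).
#' @export
read_somatic_vcf <- function(path, effect_source = NULL, tumor_sample = NULL) {
  assert_file(path, "VCF")
  vcf <- VariantAnnotation::readVcf(path)
  samples <- colnames(vcf)
  if (length(samples) == 0L) neo_stop("VCF has no sample columns")
  if (is.null(tumor_sample)) tumor_sample <- samples[length(samples)]
  if (!tumor_sample %in% samples) {
    neo_stop(sprintf("tumor sample column '%s' not found in VCF (samples: %s)",
                     tumor_sample, paste(samples, collapse = ", ")))
  }
  evcf <- VariantAnnotation::expand(vcf)
  rr <- SummarizedExperiment::rowRanges(evcf)
  n <- length(rr)

  alt <- as.character(rr$ALT)
  ref <- as.character(rr$REF)
  filt <- as.character(rr$FILTER)
  filt[is.na(filt) | filt == "."] <- "PASS"

  geno <- VariantAnnotation::geno(evcf)
  ad_ref <- rep(NA_real_, n); ad_alt <- rep(NA_real_, n)
  if ("AD" %in% names(geno)) {
    ad <- geno$AD
    if (length(dim(ad)) == 3L) {          # n x samples x (ref, alt)
      ad_ref <- as.numeric(ad[, tumor_sample, 1])
      ad_alt <- as.numeric(ad[, tumor_sample, 2])
    } else {
      adl <- ad[, tumor_sample]
      if (is.list(adl)) {
        ad_ref <- vapply(adl, function(x) as.numeric(x[1] %||% NA), 1)
        ad_alt <- vapply(adl, function(x) as.numeric(x[2] %||% NA), 1)
      }
    }
  }
  dp <- if ("DP" %in% names(geno)) as.numeric(geno$DP[, tumor_sample]) else
    rep(NA_real_, n)
  tumor_depth <- ifelse(is.na(dp), ad_ref + ad_alt, dp)
  vaf <- ad_alt / (ad_ref + ad_alt)

  bad <- is.na(tumor_depth) | is.na(vaf) | vaf < 0 | vaf > 1
  if (any(bad)) {
    warning(sprintf("dropped %d record(s) with unparseable depth/VAF", sum(bad)),
            call. = FALSE)
  }

  out <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = ref, alt = alt, filter = filt,
    tumor_depth = as.numeric(tumor_depth), vaf = as.numeric(vaf)
  )[!bad]

  out <- attach_effects(out, evcf = evcf[!bad, ], effect_source = effect_source)
  data.table::setattr(out, "class", c("neo_variants", class(out)))
  out[]
}

attach_effects <- function(out, evcf, effect_source) {
  for (cc in .effect_cols) {
    data.table::set(out, j = cc,
                    value = if (cc %in% c("protein_position", "cds_position"))
                      NA_integer_ else NA_character_)
  }
  if (is.null(effect_source)) {
    out$consequence <- "other"
    return(out)
  }
  if (file.exists(effect_source)) {
    eff <- data.table::fread(effect_source, sep = "\t",
                             colClasses = list(character = "chrom"))
    assert_cols(eff, c("chrom", "pos", "ref", "alt", "consequence_class"),
                "effect table")
    key <- paste(out$chrom, out$pos, out$ref, out$alt, sep = ":")
    ekey <- paste(eff$chrom, eff$pos, eff$ref, eff$alt, sep = ":")
    idx <- match(key, ekey)
    pick <- function(col, cast = as.character) {
      if (col %in% names(eff)) cast(eff[[col]])[idx] else
        rep(cast(NA), length(idx))
    }
    out$gene_symbol <- pick("gene_symbol")
    out$transcript_id <- pick("transcript_id")
    out$consequence <- pick("consequence_class")
    out$protein_position <- pick("protein_position", as.integer)
    out$ref_aa <- pick("ref_aa")
    out$alt_aa <- pick("alt_aa")
    out$cds_position <- pick("cds_position", as.integer)
    out$cds_ref <- pick("cds_ref")
    out$cds_alt <- pick("cds_alt")
  } else {
    out <- attach_csq(out, evcf, key = effect_source)
  }
  out$consequence[is.na(out$consequence)] <- "other"
  bad_cons <- !out$consequence %in% consequence_levels
  if (any(bad_cons)) {
    neo_stop(sprintf("unknown consequence_class value(s): %s",
                     paste(unique(out$consequence[bad_cons]), collapse = ", ")))
  }
  out
}

# Minimal VEP CSQ extraction: only the subfields the engine models.
attach_csq <- function(out, evcf, key) {
  hdr <- VariantAnnotation::info(VariantAnnotation::header(evcf))
  if (!key %in% rownames(hdr)) {
    neo_stop(sprintf("INFO key '%s' not found in VCF header and no effect table at that path",
                     key))
  }
  fmt <- sub(".*Format: ?", "", hdr[key, "Description"])
  fields <- strsplit(fmt, "|", fixed = TRUE)[[1]]
  csq <- VariantAnnotation::info(evcf)[[key]]
  get_field <- function(entry, field) {
    if (length(entry) == 0L) return(NA_character_)
    parts <- strsplit(entry[1], "|", fixed = TRUE)[[1]]
    i <- match(field, fields)
    if (is.na(i) || i > length(parts) || !nzchar(parts[i])) NA_character_
    else parts[i]
  }
  csq <- as.list(csq)
  out$gene_symbol <- vapply(csq, get_field, "", field = "SYMBOL")
  out$transcript_id <- vapply(csq, get_field, "", field = "Feature")
  out$consequence <-
    map_vep_consequence(vapply(csq, get_field, "", field = "Consequence"))
  out$protein_position <- suppressWarnings(as.integer(
    sub("[-/].*$", "", vapply(csq, get_field, "", field = "Protein_position"))))
  aa <- vapply(csq, get_field, "", field = "Amino_acids")
  out$ref_aa <- sub("/.*$", "", aa)
  out$alt_aa <- ifelse(grepl("/", aa), sub("^.*/", "", aa), NA_character_)
  out$cds_position <- suppressWarnings(as.integer(
    sub("[-/].*$", "", vapply(csq, get_field, "", field = "CDS_position"))))
  out
}

#' @export
print.neo_variants <- function(x, ...) {
  cat(sprintf("<neo_variants> %d variant record(s)\n", nrow(x)))
  y <- data.table::copy(x)
  data.table::setattr(y, "class", c("data.table", "data.frame"))
  print(y)
  invisible(x)
}
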