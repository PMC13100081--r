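# Seeded synthetic cohort: a coherent toy world (reference, somatic variants,
# coverage, expression, fusions, HLA types) with a ground-truth manifest, so
# every pipeline stage is testable without downloading anything.
#
# The stated world: 20 genes of 600 bp on one contig; 3 samples spanning the
# landscape the engine targets -- a hypermutator-like sample (many SNVs, no
# fusions), a fusion-associated SNV-low sample, and an amplification-driven
# sample carrying a DNA+RNA concordant amplified gene (depth x12, TPM x100),
# a tumor+normal shared capture spike (x10), and a transcriptional-only gene.
# Capture unevenness is emulated with a block of poorly covered genes
# (baseline 5x against 30x elsewhere).

#' Specification of the synthetic toy cohort
#'
#' @param seed Master seed; all randomness derives from it.
#' @param n_genes Number of toy genes (>= 20 expected by the default layout).
#' @param gene_length CDS length in bp (divisible by 3).
#' @param baseline_depth,low_depth Mean per-base coverage of normal / poorly
#'   captured genes.
#' @param depth_noise_sd SD of per-base Gaussian depth noise.
#' @param amp_depth_mult,amp_tpm_mult Amplified-gene multipliers.
#' @param spike_depth_mult Shared tumor+normal capture-spike multiplier.
#' @param total_mapped_reads RNA library size per sample (for FFPM).
#' @return `neo_cohort_spec` list.
#' @export
toy_cohort_spec <- function(seed = 1L, n_genes = 20L, gene_length = 600L,
                            baseline_depth = 30, low_depth = 5,
                            depth_noise_sd = 3,
                            amp_depth_mult = 12, amp_tpm_mult = 100,
                            spike_depth_mult = 10,
                            total_mapped_reads = 2e6) {
  stopifnot(gene_length %% 3L == 0L, n_genes >= 20L)
  genes <- sprintf("G%02d", seq_len(n_genes))
  structure(list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    gene_length = as.integer(gene_length),
    genes = genes,
    contig = "toychr1", gap = 100L,
    baseline_depth = baseline_depth, low_depth = low_depth,
    depth_noise_sd = depth_noise_sd,
    amp_depth_mult = amp_depth_mult, amp_tpm_mult = amp_tpm_mult,
    spike_depth_mult = spike_depth_mult,
    total_mapped_reads = total_mapped_reads,
    # gene roles in the default layout
    variant_genes = genes[1:10], fusion_genes = genes[11:12],
    lowcov_genes = genes[13:16], amp_gene = genes[17],
    spike_gene = genes[18], transonly_gene = genes[19],
    low_tpm_genes = genes[c(3, 7)],
    samples = list(
      S1 = list(n_missense = 8L, n_inframe = 2L, n_frameshift = 2L,
                n_synonymous = 3L, n_stopgain = 2L, n_nonpass = 2L,
                n_lowdepth = 2L, fusions = FALSE, special = FALSE),
      S2 = list(n_missense = 3L, n_inframe = 1L, n_frameshift = 1L,
                n_synonymous = 2L, n_stopgain = 1L, n_nonpass = 1L,
                n_lowdepth = 1L, fusions = TRUE, special = FALSE),
      S3 = list(n_missense = 2L, n_inframe = 0L, n_frameshift = 1L,
                n_synonymous = 1L, n_stopgain = 1L, n_nonpass = 1L,
                n_lowdepth = 1L, fusions = FALSE, special = TRUE)
    ),
    hla = c("A*02:01", "HLA-A*24:02", "B*07:02")
  ), class = "neo_cohort_spec")
}

gene_tx <- function(gene) sub("^G", "T", gene)

gene_starts <- function(spec) {
  starts <- 1L + (seq_len(spec$n_genes) - 1L) * (spec$gene_length + spec$gap)
  setNames(starts, spec$genes)
}

#' Build the toy reference (CDS, proteins, proteome, CDS BED)
#'
#' One transcript per gene (`G01 -> T01`), CDS sampled from sense codons
#' (so reading frames are clean), proteins by translation, proteome = all
#' reference proteins, genes tiled on one contig with fixed gaps.
#'
#' @param spec A [toy_cohort_spec()].
#' @param dir Output directory (created if needed).
#' @return List with file `paths` and in-memory `cds`, `proteins`,
#'   `bed` (`GRanges` with `gene` column), `tx2gene`.
#' @export
make_toy_reference <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(spec$seed)
  cds <- setNames(
    vapply(spec$genes, function(g) random_cds(spec$gene_length %/% 3L), ""),
    gene_tx(spec$genes))
  proteins <- setNames(vapply(cds, translate_cds, ""), names(cds))
  starts <- gene_starts(spec)
  bed <- GenomicRanges::GRanges(
    spec$contig,
    IRanges::IRanges(start = starts, width = spec$gene_length))
  bed$gene <- spec$genes
  paths <- list(
    cds_fasta = file.path(dir, "cds.fasta"),
    protein_fasta = file.path(dir, "proteins.fasta"),
    proteome_fasta = file.path(dir, "proteome.fasta"),
    cds_bed = file.path(dir, "cds.bed")
  )
  write_fasta(cds, paths$cds_fasta)
  write_fasta(proteins, paths$protein_fasta)
  write_fasta(setNames(proteins, paste0("ref|", names(proteins))),
              paths$proteome_fasta)
  write_bed(bed, paths$cds_bed)
  list(paths = paths, cds = cds, proteins = proteins, bed = bed,
       tx2gene = setNames(spec$genes, names(cds)))
}

# --- variant planting ------------------------------------------------------

plant_snv <- function(cds, want = c("missense", "synonymous", "stop_gain"),
                      used_codons) {
  want <- match.arg(want)
  n_codon <- nchar(cds) %/% 3L
  for (attempt in seq_len(500L)) {
    codon_i <- sample(3:(n_codon - 3L), 1L)
    if (codon_i %in% used_codons) next
    within <- sample(1:3, 1L)
    cpos <- (codon_i - 1L) * 3L + within
    ref_b <- substr(cds, cpos, cpos)
    codon <- substr(cds, (codon_i - 1L) * 3L + 1L, codon_i * 3L)
    ref_aa <- unname(Biostrings::GENETIC_CODE[codon])
    for (alt_b in sample(setdiff(c("A", "C", "G", "T"), ref_b))) {
      alt_codon <- codon
      substr(alt_codon, within, within) <- alt_b
      alt_aa <- unname(Biostrings::GENETIC_CODE[alt_codon])
      ok <- switch(want,
        missense = alt_aa != ref_aa && alt_aa != "*",
        synonymous = alt_aa == ref_aa,
        stop_gain = alt_aa == "*")
      if (ok) {
        return(list(codon_i = codon_i, cds_pos = cpos, ref = ref_b,
                    alt = alt_b, ref_aa = ref_aa, alt_aa = alt_aa,
                    protein_position = codon_i))
      }
    }
  }
  neo_stop("could not plant requested SNV", class = "neo_stage_error")
}

plant_indel <- function(cds, type = c("frameshift", "inframe"), used_codons) {
  type <- match.arg(type)
  n_codon <- nchar(cds) %/% 3L
  for (attempt in seq_len(500L)) {
    codon_i <- sample(5:(n_codon - 20L), 1L)
    if (any((codon_i + 0:1) %in% used_codons)) next
    cpos <- (codon_i - 1L) * 3L + 1L
    anchor <- substr(cds, cpos, cpos)
    if (type == "frameshift") {
      ref <- substr(cds, cpos, cpos + 1L)   # delete 1 nt
      alt <- anchor
      mut <- paste0(substr(cds, 1, cpos), substr(cds, cpos + 2L, nchar(cds)))
    } else {
      ins <- random_cds(1L)                 # insert one sense codon
      ref <- anchor
      alt <- paste0(anchor, ins)
      mut <- paste0(substr(cds, 1, cpos), ins,
                    substr(cds, cpos + 1L, nchar(cds)))
    }
    ref_aa <- translate_cds(cds); mut_aa <- translate_cds(mut)
    d <- common_prefix_len(ref_aa, mut_aa)
    novel <- nchar(mut_aa) - d
    if (type == "frameshift" && novel < 3L) next  # want a visible novel tail
    if (type == "inframe" && identical(ref_aa, mut_aa)) next
    return(list(codon_i = codon_i, cds_pos = cpos, ref = ref, alt = alt))
  }
  neo_stop("could not plant requested indel", class = "neo_stage_error")
}

write_toy_vcf <- function(records, path, contig, contig_len) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", contig, contig_len),
    "##FILTER=<ID=PASS,Description=\"All filters passed\">",
    "##FILTER=<ID=germline,Description=\"Evidence of germline origin\">",
    "##FILTER=<ID=weak_evidence,Description=\"Weak somatic evidence\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           "NORMAL\tTUMOR")
  )
  body <- vapply(records, function(r) {
    sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t.\tAD:DP\t%d,0:%d\t%d,%d:%d",
            contig, r$pos, r$ref, r$alt, r$filter,
            r$normal_depth, r$normal_depth,
            r$ref_count, r$alt_count, r$tumor_depth)
  }, "")
  writeLines(c(hdr, body), path)
  invisible(path)
}

# Depth model for one sample: baseline per gene with per-base noise,
# multipliers for amplified / spiked genes, tumor and normal tracks.
sample_depth_tables <- function(spec, sample_cfg, site_overrides) {
  starts <- gene_starts(spec)
  rows_t <- vector("list", spec$n_genes)
  rows_n <- vector("list", spec$n_genes)
  for (i in seq_len(spec$n_genes)) {
    g <- spec$genes[i]
    base <- if (g %in% spec$lowcov_genes) spec$low_depth else
      spec$baseline_depth
    mult_t <- 1; mult_n <- 1
    if (isTRUE(sample_cfg$special)) {
      if (g == spec$amp_gene) mult_t <- spec$amp_depth_mult
      if (g == spec$spike_gene) { mult_t <- spec$spike_depth_mult
                                  mult_n <- spec$spike_depth_mult }
    }
    pos <- starts[g] + 0:(spec$gene_length - 1L)
    noise_t <- round(stats::rnorm(spec$gene_length, 0, spec$depth_noise_sd))
    noise_n <- round(stats::rnorm(spec$gene_length, 0, spec$depth_noise_sd))
    rows_t[[i]] <- data.table::data.table(
      contig = spec$contig, pos = pos,
      depth = pmax(0L, as.integer(round(base * mult_t)) + as.integer(noise_t)))
    rows_n[[i]] <- data.table::data.table(
      contig = spec$contig, pos = pos,
      depth = pmax(0L, as.integer(round(base * mult_n)) + as.integer(noise_n)))
  }
  tumor <- data.table::rbindlist(rows_t)
  normal <- data.table::rbindlist(rows_n)
  for (ov in site_overrides) {
    tumor[pos == ov$pos, depth := ov$tumor_depth]
    normal[pos == ov$pos, depth := ov$normal_depth]
  }
  list(tumor = tumor, normal = normal)
}

fusion_junction <- function(cds5, cds3, n_codons = 10L) {
  # codon-boundary slices from the interior of each partner CDS
  part5 <- substr(cds5, 31L, 30L + 3L * n_codons)
  part3 <- substr(cds3, 61L, 60L + 3L * n_codons)
  list(seq = paste0(part5, part3), offset = 3L * n_codons,
       marked = paste0(part5, "|", part3))
}

write_toy_fusions <- function(rows, path) {
  hdr <- c("#gene1", "gene2", "breakpoint1", "breakpoint2", "split_reads1",
           "split_reads2", "discordant_mates", "confidence", "reading_frame",
           "transcript_sequence")
  lines <- vapply(rows, function(r) {
    paste(r$gene1, r$gene2, r$bp1, r$bp2, r$sr1, r$sr2, r$dm, r$confidence,
          r$frame, r$tseq, sep = "\t")
  }, "")
  writeLines(c(paste(hdr, collapse = "\t"), lines), path)
  invisible(path)
}

#' Generate all per-sample inputs plus the ground-truth manifest
#'
#' Writes, per sample: somatic VCF + companion effect table, tumor and
#' normal depth tables, transcript abundance table (with gene column),
#' Arriba-style fusion table, and an HLA list; plus a cohort `manifest.json`
#' for [run_pipeline()] and a `ground_truth.tsv` with the planted counts
#' (epitope-eligible variants, TMB-eligible variants, callable bases, TMB,
#' Ti/Tv, retained fusions, expressed gate-passing sources).
#'
#' @param spec A [toy_cohort_spec()].
#' @param ref Result of [make_toy_reference()].
#' @param dir Output directory.
#' @return List with `paths` per sample, `manifest` (list form),
#'   `ground_truth` (`data.table`).
#' @export
make_somatic_inputs <- function(spec, ref, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  starts <- gene_starts(spec)
  contig_len <- max(starts) + spec$gene_length + spec$gap

  # --- expression (seed stream 3): per-gene base TPM shared structure ----
  set.seed(spec$seed + 3L)
  base_tpm <- setNames(round(stats::rlnorm(spec$n_genes, log(8), 0.7), 2),
                       spec$genes)
  base_tpm[spec$low_tpm_genes] <- c(0.50, 0.20)
  base_tpm[spec$transonly_gene] <- 2.0

  gt_rows <- list()
  sample_paths <- list()
  sample_names <- names(spec$samples)

  for (si in seq_along(spec$samples)) {
    sname <- sample_names[si]
    cfg <- spec$samples[[si]]
    set.seed(spec$seed + 10L * si)

    # ---- plant variants ------------------------------------------------
    used <- lapply(setNames(nm = spec$variant_genes), function(g) integer(0))
    recs <- list(); eff <- list()
    add_rec <- function(gene, kind, filter = "PASS", site_depth = NULL,
                        lowdepth = FALSE) {
      tx <- gene_tx(gene)
      cds <- ref$cds[[tx]]
      if (kind %in% c("missense", "synonymous", "stop_gain")) {
        pl <- plant_snv(cds, kind, used[[gene]])
        used[[gene]] <<- c(used[[gene]], pl$codon_i)
        cds_pos <- pl$cds_pos; refb <- pl$ref; altb <- pl$alt
        effrow <- data.table::data.table(
          gene_symbol = gene, transcript_id = tx, consequence_class = kind,
          protein_position = pl$protein_position, ref_aa = pl$ref_aa,
          alt_aa = pl$alt_aa, cds_position = cds_pos, cds_ref = refb,
          cds_alt = altb)
      } else {
        pl <- plant_indel(cds, if (kind == "frameshift") "frameshift" else
          "inframe", used[[gene]])
        used[[gene]] <<- c(used[[gene]], pl$codon_i + 0:1)
        cds_pos <- pl$cds_pos; refb <- pl$ref; altb <- pl$alt
        effrow <- data.table::data.table(
          gene_symbol = gene, transcript_id = tx,
          consequence_class = if (kind == "frameshift") "frameshift" else
            "inframe_indel",
          protein_position = NA_integer_, ref_aa = NA_character_,
          alt_aa = NA_character_, cds_position = cds_pos, cds_ref = refb,
          cds_alt = altb)
      }
      depth <- site_depth %||% sample(20:60, 1L)
      if (lowdepth) depth <- sample(4:9, 1L)
      vaf_target <- stats::runif(1, 0.2, 0.9)
      alt_count <- max(1L, round(vaf_target * depth))
      ref_count <- depth - alt_count
      pos <- starts[gene] + cds_pos - 1L
      recs[[length(recs) + 1L]] <<- list(
        pos = pos, ref = refb, alt = altb, filter = filter,
        tumor_depth = depth, ref_count = ref_count, alt_count = alt_count,
        normal_depth = spec$baseline_depth, gene = gene, kind = kind,
        lowdepth = lowdepth)
      eff[[length(eff) + 1L]] <<- data.table::data.table(
        chrom = spec$contig, pos = pos, ref = refb, alt = altb, effrow)
    }

    vg <- spec$variant_genes
    pick_gene <- function() sample(vg, 1L)
    for (k in seq_len(cfg$n_missense)) add_rec(pick_gene(), "missense")
    for (k in seq_len(cfg$n_inframe)) add_rec(pick_gene(), "inframe")
    for (k in seq_len(cfg$n_frameshift)) add_rec(pick_gene(), "frameshift")
    for (k in seq_len(cfg$n_synonymous)) add_rec(pick_gene(), "synonymous")
    for (k in seq_len(cfg$n_stopgain)) add_rec(pick_gene(), "stop_gain")
    for (k in seq_len(cfg$n_nonpass)) {
      add_rec(pick_gene(), "missense", filter = "germline;weak_evidence")
    }
    for (k in seq_len(cfg$n_lowdepth)) {
      add_rec(pick_gene(), "missense", lowdepth = TRUE)
    }
    recs <- recs[order(vapply(recs, function(r) r$pos, 1))]
    eff_dt <- data.table::rbindlist(eff)
    data.table::setorder(eff_dt, pos)

    # ---- depth tracks (site depths forced to match the VCF) -------------
    overrides <- lapply(recs, function(r) {
      list(pos = r$pos, tumor_depth = r$tumor_depth,
           normal_depth = r$normal_depth)
    })
    depths <- sample_depth_tables(spec, cfg, overrides)

    # ---- expression table ----------------------------------------------
    tpm <- base_tpm
    if (isTRUE(cfg$special)) {
      tpm[spec$amp_gene] <- base_tpm[spec$amp_gene] * spec$amp_tpm_mult
      tpm[spec$transonly_gene] <- 200
    }
    ab <- data.table::data.table(
      target_id = gene_tx(spec$genes), tpm = unname(tpm),
      gene = spec$genes)
    # split the first gene across two transcripts (tests TPM aggregation)
    extra <- data.table::data.table(target_id = "T01b",
                                    tpm = round(tpm[[1]] / 3, 4),
                                    gene = spec$genes[1])
    ab$tpm[1] <- round(tpm[[1]] - extra$tpm, 4)
    ab <- rbind(ab, extra)

    # ---- fusions --------------------------------------------------------
    set.seed(spec$seed + 100L + si)
    fus_rows <- list(); retained <- 0L; retained_labels <- character(0)
    if (isTRUE(cfg$fusions)) {
      j1 <- fusion_junction(ref$cds[[gene_tx(spec$fusion_genes[1])]],
                            ref$cds[[gene_tx(spec$fusion_genes[2])]])
      j2 <- fusion_junction(ref$cds[[gene_tx(spec$variant_genes[1])]],
                            ref$cds[[gene_tx(spec$fusion_genes[1])]])
      bp <- function(g) sprintf("%s:%d", spec$contig, unname(starts[g]))
      fus_rows <- list(
        list(gene1 = spec$fusion_genes[1], gene2 = spec$fusion_genes[2],
             bp1 = bp(spec$fusion_genes[1]), bp2 = bp(spec$fusion_genes[2]),
             sr1 = 4L, sr2 = 3L, dm = 6L, confidence = "high",
             frame = "in-frame", tseq = j1$marked),
        list(gene1 = spec$variant_genes[1], gene2 = spec$fusion_genes[1],
             bp1 = bp(spec$variant_genes[1]), bp2 = bp(spec$fusion_genes[1]),
             sr1 = 2L, sr2 = 1L, dm = 1L, confidence = "high",
             frame = "in-frame", tseq = j2$marked),          # low support
        list(gene1 = spec$fusion_genes[2], gene2 = spec$variant_genes[2],
             bp1 = bp(spec$fusion_genes[2]), bp2 = bp(spec$variant_genes[2]),
             sr1 = 8L, sr2 = 4L, dm = 5L, confidence = "medium",
             frame = "in-frame", tseq = j1$marked),          # not high
        list(gene1 = spec$fusion_genes[1], gene2 = spec$variant_genes[3],
             bp1 = bp(spec$fusion_genes[1]), bp2 = bp(spec$variant_genes[3]),
             sr1 = 7L, sr2 = 6L, dm = 2L, confidence = "high",
             frame = "out-of-frame", tseq = j1$marked)       # frame fails
      )
      retained <- 1L
      retained_labels <- paste0(spec$fusion_genes[1], "::",
                                spec$fusion_genes[2])
    }

    # ---- write ----------------------------------------------------------
    p <- list(
      vcf = file.path(dir, paste0(sname, ".vcf")),
      effects = file.path(dir, paste0(sname, ".effects.tsv")),
      tumor_depth = file.path(dir, paste0(sname, ".tumor.depth.tsv")),
      normal_depth = file.path(dir, paste0(sname, ".normal.depth.tsv")),
      abundance = file.path(dir, paste0(sname, ".abundance.tsv")),
      fusions = file.path(dir, paste0(sname, ".fusions.tsv")),
      hla = file.path(dir, paste0(sname, ".hla.txt")),
      truth_variants = file.path(dir, paste0(sname, ".truth_variants.tsv"))
    )
    write_toy_vcf(recs, p$vcf, spec$contig, contig_len)
    data.table::fwrite(eff_dt, p$effects, sep = "\t", eol = "\n")
    data.table::fwrite(depths$tumor, p$tumor_depth, sep = "\t",
                       col.names = FALSE, eol = "\n")
    data.table::fwrite(depths$normal, p$normal_depth, sep = "\t",
                       col.names = FALSE, eol = "\n")
    data.table::fwrite(ab, p$abundance, sep = "\t", eol = "\n")
    write_toy_fusions(fus_rows, p$fusions)
    writeLines(spec$hla, p$hla)
    truth <- data.table::rbindlist(lapply(recs, function(r) {
      data.table::data.table(
        chrom = spec$contig, pos = r$pos, ref = r$ref, alt = r$alt,
        filter = r$filter, tumor_depth = r$tumor_depth,
        vaf = r$alt_count / r$tumor_depth, gene = r$gene, kind = r$kind)
    }))
    data.table::fwrite(truth, p$truth_variants, sep = "\t", eol = "\n")
    sample_paths[[sname]] <- p

    # ---- ground truth (generator arithmetic, no engine calls) ----------
    cds_pos_all <- depths$tumor  # tumor CDS-only track by construction
    callable_bases <- sum(cds_pos_all$depth >= 10L)
    kinds <- vapply(recs, function(r) r$kind, "")
    pass <- vapply(recs, function(r) r$filter == "PASS", TRUE)
    deep <- vapply(recs, function(r) r$tumor_depth >= 10L, TRUE)
    epi_kind <- kinds %in% c("missense", "inframe", "frameshift")
    tmb_kind <- kinds %in% c("missense", "inframe", "frameshift", "stop_gain")
    n_epi <- sum(pass & deep & epi_kind)
    n_tmb <- sum(pass & deep & tmb_kind)
    snv <- vapply(recs, function(r) nchar(r$ref) == 1L && nchar(r$alt) == 1L,
                  TRUE)
    qual_snv <- snv & pass & deep
    ti <- sum(qual_snv & vapply(recs, function(r) {
      paste0(r$ref, r$alt) %in% c("AG", "GA", "CT", "TC")
    }, TRUE))
    tv <- sum(qual_snv) - ti
    genes_of <- vapply(recs, function(r) r$gene, "")
    expressed <- tpm[genes_of] >= 1
    # gene 1's TPM is split across transcripts; gene-level value unchanged
    n_gated_sources <- sum(pass & deep & epi_kind & expressed) + retained
    gt_rows[[sname]] <- data.table::data.table(
      sample = sname,
      metric = c("n_eligible_epitope_variants", "n_tmb_eligible",
                 "callable_bases", "tmb", "titv", "n_fusions_total",
                 "n_fusions_retained", "n_gated_sources"),
      value = c(n_epi, n_tmb, callable_bases, n_tmb / (callable_bases / 1e6),
                if (tv == 0L) NA_real_ else ti / tv, length(fus_rows),
                retained, n_gated_sources)
    )
  }

  manifest <- list(
    reference = lapply(ref$paths, normalizePath),
    samples = lapply(sample_names, function(sname) {
      c(list(name = sname,
             total_mapped_reads = spec$total_mapped_reads),
        lapply(sample_paths[[sname]], normalizePath))
    })
  )
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  gt <- data.table::rbindlist(gt_rows)
  gt_path <- file.path(dir, "ground_truth.tsv")
  data.table::fwrite(gt, gt_path, sep = "\t", eol = "\n")
  list(paths = sample_paths, manifest = manifest,
       manifest_path = manifest_path, ground_truth = gt, gt_path = gt_path)
}

#' Simulate the complete toy cohort
#'
#' Convenience wrapper: builds the reference and all per-sample inputs under
#' `dir`, returning paths, the run manifest and the ground-truth table.
#' Fixed seed implies byte-identical outputs.
#'
#' @param spec A [toy_cohort_spec()].
#' @param dir Output directory.
#' @return List: `reference`, plus everything from [make_somatic_inputs()].
#' @export
simulate_cohort <- function(spec = toy_cohort_spec(), dir) {
  ref <- make_toy_reference(spec, dir)
  out <- make_somatic_inputs(spec, ref, dir)
  c(list(reference = ref), out)
}
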