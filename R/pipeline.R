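#' Run configuration
#'
#' Collects every tunable threshold of the engine with its conventional
#' default: callable/variant depth 10x, expression gates (TPM >= 1,
#' FFPM >= 1), peptide lengths 8-11, strong/weak binder cutoffs 0.5 / 2.0
#' percent rank, logistic slope 5 with inflection at 2, tanh expression
#' scales (TPM/10, FFPM/2), fusion filters (support >= 5, high confidence,
#' in-frame) and concordance thresholds.
#'
#' @param min_depth Minimum depth for callable territory and variant sites.
#' @param min_tpm,min_ffpm Expression gate minima.
#' @param lengths Peptide window lengths (within 8..11).
#' @param strong_rank,weak_rank Binder class boundaries.
#' @param logistic_slope,logistic_inflection Logistic transform parameters.
#' @param tanh_scales Named scales for [expression_component()].
#' @param fusion_filter A [fusion_filter_config()].
#' @param concordance A [concordance_thresholds()] list.
#' @param ffpm_mode Support definition for [compute_ffpm()].
#' @param predictor Registered binding-predictor name.
#' @param seed Seed recorded with the run.
#' @return `neo_config` list.
#' @export
neo_config <- function(min_depth = 10L, min_tpm = 1, min_ffpm = 1,
                       lengths = 8:11, strong_rank = 0.5, weak_rank = 2.0,
                       logistic_slope = 5, logistic_inflection = 2,
                       tanh_scales = c(TPM = 10, FFPM = 2),
                       fusion_filter = fusion_filter_config(),
                       concordance = concordance_thresholds(),
                       ffpm_mode = "junction_plus_discordant",
                       predictor = "stub", seed = 1L) {
  stopifnot(min_depth >= 1, min_tpm > 0, min_ffpm > 0,
            all(lengths >= 8L & lengths <= 11L),
            strong_rank > 0, weak_rank > strong_rank,
            logistic_slope > 0, logistic_inflection > 0,
            all(tanh_scales > 0))
  structure(list(
    min_depth = as.integer(min_depth), min_tpm = min_tpm,
    min_ffpm = min_ffpm, lengths = as.integer(lengths),
    strong_rank = strong_rank, weak_rank = weak_rank,
    logistic_slope = logistic_slope,
    logistic_inflection = logistic_inflection,
    tanh_scales = tanh_scales, fusion_filter = fusion_filter,
    concordance = concordance, ffpm_mode = ffpm_mode,
    predictor = predictor, seed = as.integer(seed)
  ), class = "neo_config")
}

#' Serialize / restore a run configuration (JSON)
#' @param config `neo_config` list.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "neo_config"))
  x <- unclass(config)
  x$fusion_filter <- unclass(x$fusion_filter)
  x$tanh_scales <- as.list(x$tanh_scales)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  assert_file(path, "config")
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  neo_config(
    min_depth = x$min_depth, min_tpm = x$min_tpm, min_ffpm = x$min_ffpm,
    lengths = x$lengths, strong_rank = x$strong_rank,
    weak_rank = x$weak_rank, logistic_slope = x$logistic_slope,
    logistic_inflection = x$logistic_inflection,
    tanh_scales = unlist(x$tanh_scales),
    fusion_filter = do.call(fusion_filter_config, as.list(x$fusion_filter)),
    concordance = do.call(concordance_thresholds, as.list(x$concordance)),
    ffpm_mode = x$ffpm_mode, predictor = x$predictor, seed = x$seed
  )
}

#' Read a cohort manifest (JSON)
#'
#' The manifest lists the shared reference files (`cds_fasta`,
#' `protein_fasta`, `proteome_fasta`, `cds_bed`) and one entry per sample
#' (`name`, `vcf`, `effects`, `tumor_depth`, `normal_depth`, `abundance`,
#' `fusions`, `hla`, `total_mapped_reads`). Relative paths are resolved
#' against the manifest's directory.
#'
#' @param path Manifest JSON path.
#' @return List with `reference` and `samples`.
#' @export
read_manifest <- function(path) {
  assert_file(path, "manifest")
  m <- jsonlite::read_json(path, simplifyVector = FALSE)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.character(p) && !file.exists(p) &&
        file.exists(file.path(base, p))) file.path(base, p) else p
  }
  m$reference <- lapply(m$reference, resolve)
  m$samples <- lapply(m$samples, function(s) {
    s[setdiff(names(s), c("name", "total_mapped_reads"))] <-
      lapply(s[setdiff(names(s), c("name", "total_mapped_reads"))], resolve)
    s
  })
  m
}

stage <- function(log_con, sample, name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e) {
    msg <- sprintf("[%s] stage '%s' failed: %s", sample, name,
                   conditionMessage(e))
    if (!is.null(log_con)) writeLines(msg, log_con)
    neo_stop(msg, class = "neo_stage_error")
  })
  msg <- sprintf("[%s] %-18s ok (%0.2fs)%s", sample, name,
                 proc.time()[["elapsed"]] - t0,
                 if (!is.null(attr(res, "n_records"))) {
                   sprintf(" n=%d", attr(res, "n_records"))
                 } else "")
  if (!is.null(log_con)) writeLines(msg, log_con)
  message(msg)
  res
}

with_n <- function(x, n) { attr(x, "n_records") <- as.integer(n); x }

#' Run the full per-cohort pipeline
#'
#' Stages per sample, in order: callable territory -> TMB/Ti-Tv -> epitope
#' variant selection -> variant peptide generation -> fusion filtering and
#' junction peptides -> binding prediction -> component scoring -> ranking;
#' then a cohort-level DNA-RNA concordance report (the per-gene cohort TPM
#' reference is the median across the manifest's samples). Writes
#' `tmb_report.tsv`, `candidates.tsv`, `concordance.tsv` and `run.log`
#' under `out_dir`; all outputs are deterministic for fixed inputs and
#' configuration.
#'
#' @param manifest Manifest path (JSON) or pre-parsed list
#'   (see [read_manifest()]).
#' @param config A [neo_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisible list: `tmb` (per-sample `neo_tmb`), `candidates`
#'   (ranked `neo_scored` table), `concordance` table, and output `paths`.
#' @export
run_pipeline <- function(manifest, config = neo_config(), out_dir) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)

  ref <- manifest$reference
  proteins <- stage(log_con, "cohort", "reference",
                    read_fasta(ref$protein_fasta))
  cds_seqs <- read_fasta(ref$cds_fasta)
  proteome <- build_proteome(ref$proteome_fasta)
  cds <- read_bed(ref$cds_bed)
  predictor <- get_predictor(config$predictor)

  tmb_list <- list(); scored_list <- list(); expr_list <- list()
  depth_cache <- list()

  for (s in manifest$samples) {
    sname <- s$name
    tumor_depth <- stage(log_con, sname, "depth",
                         read_depth_table(s$tumor_depth))
    normal_depth <- read_depth_table(s$normal_depth)
    depth_cache[[sname]] <- list(tumor = tumor_depth, normal = normal_depth)
    territory <- stage(log_con, sname, "callable",
                       compute_callable(tumor_depth, cds, config$min_depth))
    variants <- stage(log_con, sname, "variants", {
      v <- read_somatic_vcf(s$vcf, effect_source = s$effects)
      with_n(v, nrow(v))
    })
    tmb_list[[sname]] <- stage(log_con, sname, "tmb",
      compute_tmb(variants, territory, depth = tumor_depth, cds = cds,
                  min_depth = config$min_depth))
    eligible <- stage(log_con, sname, "select_variants", {
      e <- select_epitope_variants(variants, config$min_depth)
      with_n(e, nrow(e))
    })
    pep_var <- stage(log_con, sname, "variant_peptides", {
      p <- variant_peptides(eligible, proteins, cds_seqs,
                            lengths = config$lengths)
      with_n(p, nrow(p))
    })
    fusions <- stage(log_con, sname, "fusions", {
      f <- filter_fusions(read_fusion_table(s$fusions),
                          config$fusion_filter)
      with_n(f, nrow(f))
    })
    ffpm <- if (nrow(fusions)) {
      setNames(compute_ffpm(fusions, s$total_mapped_reads,
                            mode = config$ffpm_mode),
               paste0(fusions$gene5, "::", fusions$gene3))
    } else numeric(0)
    pep_fus <- stage(log_con, sname, "fusion_peptides", {
      p <- if (nrow(fusions)) {
        data.table::rbindlist(lapply(seq_len(nrow(fusions)), function(i) {
          fusion_peptides(fusions[i], lengths = config$lengths)
        }))
      } else empty_peptides()
      with_n(p, nrow(p))
    })
    peptides <- rbind(pep_var, pep_fus)
    abundance <- read_abundance(s$abundance)
    gexpr <- gene_tpm(abundance)
    expr_list[[sname]] <- gexpr
    alleles <- read_hla_list(s$hla)
    binding <- stage(log_con, sname, "binding", {
      pep_all <- unique(c(peptides$sequence,
                          stats::na.omit(peptides$wildtype_counterpart)))
      b <- if (length(pep_all)) predictor(pep_all, alleles) else
        stub_predict("ACDEFGHK", alleles)[0]
      with_n(b, nrow(b))
    })
    scored_list[[sname]] <- stage(log_con, sname, "score", {
      vafs <- setNames(eligible$vaf, variant_key(eligible))
      sc <- rank_candidates(score_candidates(
        peptides, binding, alleles, gexpr, fusion_ffpm = ffpm,
        vaf_by_variant = vafs, proteome = proteome, config = config,
        sample = sname))
      with_n(sc, nrow(sc))
    })
  }

  # cohort-level concordance: per-gene median TPM as the reference
  genes <- unique(cds$gene)
  conc <- if (!is.null(genes)) {
    ref_tpm <- vapply(genes, function(g) {
      stats::median(vapply(expr_list, function(e)
        if (g %in% names(e)) unname(e[g]) else 0, 1))
    }, 1)
    data.table::rbindlist(lapply(names(depth_cache), function(sname) {
      out <- concordance_report(depth_cache[[sname]]$tumor,
                                depth_cache[[sname]]$normal, cds,
                                expr_list[[sname]],
                                cohort_reference = ref_tpm,
                                thresholds = config$concordance)
      data.table::data.table(sample = sname, out)
    }))
  } else NULL

  paths <- list(tmb = file.path(out_dir, "tmb_report.tsv"),
                candidates = file.path(out_dir, "candidates.tsv"),
                concordance = file.path(out_dir, "concordance.tsv"),
                log = log_path)
  tmb_dt <- data.table::rbindlist(lapply(names(tmb_list), function(sname) {
    r <- tmb_list[[sname]]
    data.table::data.table(sample = sname, nonsyn_count = r$nonsyn_count,
                           callable_mb = r$callable_mb, tmb = r$tmb,
                           titv = r$titv,
                           breadth_at_threshold = r$breadth_at_threshold)
  }))
  write_tsv_deterministic(tmb_dt, paths$tmb,
                          num_cols = c("callable_mb", "tmb", "titv",
                                       "breadth_at_threshold"))
  candidates <- data.table::rbindlist(Filter(function(x) nrow(x) > 0,
                                             scored_list))
  write_candidates_table(candidates, paths$candidates)
  if (!is.null(conc)) {
    write_tsv_deterministic(conc, paths$concordance,
      num_cols = c("tumor_locus_depth", "normal_locus_depth",
                   "tumor_background_depth", "normal_background_depth",
                   "tumor_ratio", "normal_ratio", "tpm",
                   "cohort_tpm_reference"))
  }
  invisible(list(tmb = tmb_list, candidates = candidates,
                 concordance = conc, paths = paths))
}
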