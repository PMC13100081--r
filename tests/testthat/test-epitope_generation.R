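test_that("translate_cds follows the standard code, stops and ambiguity", {
  expect_equal(translate_cds("ATGGCC"), "MA")
  expect_equal(translate_cds("ATGTAAGCC"), "M")
  expect_equal(translate_cds("ATGGC"), "M")     # trailing partial codon
  expect_equal(translate_cds("ATGNCCGGG"), "MXG")
  expect_equal(translate_cds(""), "")
  # random CDS agrees with an independent codon-table implementation
  with_seed(41, {
    for (i in 1:25) {
      n_codon <- sample(5:60, 1)
      cds <- paste(sample(c("A", "C", "G", "T"), 3 * n_codon, TRUE),
                   collapse = "")
      oracle <- as.character(suppressWarnings(
        Biostrings::translate(Biostrings::DNAString(cds),
                              no.init.codon = TRUE)))
      oracle <- strsplit(oracle, "*", fixed = TRUE)[[1]][1]
      if (is.na(oracle)) oracle <- ""
      expect_equal(translate_cds(cds), oracle)
    }
  })
})

test_that("epitope variant selection applies the documented filters", {
  v <- data.table::data.table(
    chrom = "c", pos = 1:6 * 10L, ref = "A", alt = "G",
    filter = c("PASS", "PASS", "PASS", "PASS", "weak_evidence", "PASS"),
    tumor_depth = c(30, 30, 30, 9, 30, 30), vaf = 0.4,
    consequence = c("missense", "stop_gain", "synonymous", "missense",
                    "missense", "frameshift"))
  data.table::setattr(v, "class", c("neo_variants", class(v)))
  kept <- select_epitope_variants(v)
  expect_equal(kept$pos, c(10L, 60L))
  expect_equal(kept$consequence, c("missense", "frameshift"))
})

test_that("missense context substitutes exactly one residue", {
  v <- list(chrom = "c", pos = 1L, ref = "T", alt = "C", gene_symbol = "G",
            transcript_id = "TX", protein_position = 5L, ref_aa = "F",
            alt_aa = "L")
  ctx <- build_missense_context(v, c(TX = "ACDEFGHIK"))
  expect_equal(ctx$mutant_sequence, "ACDELGHIK")
  expect_equal(c(ctx$span_start, ctx$span_end), c(5L, 5L))
  expect_equal(ctx$wildtype_sequence, "ACDEFGHIK")
  # annotation/sequence mismatch is a hard error
  v$ref_aa <- "W"
  expect_error(build_missense_context(v, c(TX = "ACDEFGHIK")),
               "out of sync")
  # random substitutions: exactly one differing residue
  with_seed(43, {
    for (i in 1:20) {
      prot <- random_protein(sample(30:80, 1))
      p <- sample(nchar(prot), 1)
      old <- substr(prot, p, p)
      new <- sample(setdiff(aa20, old), 1)
      vv <- list(chrom = "c", pos = 1L, ref = "A", alt = "C",
                 gene_symbol = "G", transcript_id = "TX",
                 protein_position = p, ref_aa = old, alt_aa = new)
      ctx <- build_missense_context(vv, c(TX = prot))
      diffs <- which(strsplit(ctx$mutant_sequence, "")[[1]] !=
                       strsplit(prot, "")[[1]])
      expect_equal(diffs, p)
    }
  })
})

test_that("frameshift context spans first novel residue to new terminus", {
  with_seed(44, {
    cds <- neoforge:::random_cds(40, terminal_stop = TRUE)
  })
  v <- list(chrom = "c", pos = 1L, ref = "X", alt = "X", gene_symbol = "G",
            transcript_id = "TX", cds_position = 31L,
            cds_ref = substr(cds, 31, 32), cds_alt = substr(cds, 31, 31))
  ctx <- build_frameshift_context(v, setNames(list(cds), "TX"))
  ref_aa <- translate_cds(cds)
  mut_aa <- translate_cds(paste0(substr(cds, 1, 31),
                                 substr(cds, 33, nchar(cds))))
  expect_equal(ctx$mutant_sequence, mut_aa)
  # prefix before the span matches reference, span start differs
  expect_equal(substr(ctx$mutant_sequence, 1, ctx$span_start - 1),
               substr(ref_aa, 1, ctx$span_start - 1))
  expect_equal(ctx$span_end, nchar(mut_aa))
  expect_true(substr(mut_aa, ctx$span_start, ctx$span_start) !=
                substr(ref_aa, ctx$span_start, ctx$span_start) ||
                ctx$span_start > nchar(ref_aa))
  # in-frame indel routed here is a contract error
  v_if <- v
  v_if$cds_ref <- substr(cds, 31, 31)
  v_if$cds_alt <- paste0(substr(cds, 31, 31), "GCTAAA")
  expect_error(build_frameshift_context(v_if, setNames(list(cds), "TX")),
               "in-frame")
})

test_that("in-frame contexts mark insertions and deletion joints", {
  cds <- paste(rep("GCT", 30), collapse = "")    # poly-alanine, 30 codons
  # insertion of two codons after codon 10
  v_ins <- list(chrom = "c", pos = 1L, ref = "X", alt = "X",
                gene_symbol = "G", transcript_id = "TX", cds_position = 30L,
                cds_ref = "T", cds_alt = "TTGGAGG")
  ctx <- build_inframe_context(v_ins, c(TX = cds))
  expect_equal(ctx$span_end - ctx$span_start + 1L, 2L)
  expect_equal(nchar(ctx$mutant_sequence), 32L)
  # deletion of one codon: joint span, windows must straddle it
  v_del <- list(chrom = "c", pos = 1L, ref = "X", alt = "X",
                gene_symbol = "G", transcript_id = "TX", cds_position = 30L,
                cds_ref = substr(cds, 30, 33), cds_alt = "T")
  # deleting an alanine from poly-alanine is protein-silent
  expect_null(build_inframe_context(v_del, c(TX = cds)))
  cds2 <- paste(c(rep("GCT", 10), "TGG", rep("AAA", 10)), collapse = "")
  v_del2 <- list(chrom = "c", pos = 1L, ref = "X", alt = "X",
                 gene_symbol = "G", transcript_id = "TX", cds_position = 30L,
                 cds_ref = substr(cds2, 30, 33), cds_alt = substr(cds2, 30, 30))
  ctx2 <- build_inframe_context(v_del2, c(TX = cds2))
  expect_equal(ctx2$span_type, "joint")
  peps <- enumerate_peptides(ctx2)
  wend <- peps$window_start + peps$length - 1L
  expect_true(all(peps$window_start <= ctx2$span_start &
                    wend >= ctx2$span_start + 1L))
  # random in-frame indels change protein length by (indel nt)/3
  with_seed(45, {
    for (i in 1:15) {
      k <- sample(1:3, 1)
      cdsr <- neoforge:::random_cds(40)
      ins <- neoforge:::random_cds(k)
      vv <- list(chrom = "c", pos = 1L, ref = "X", alt = "X",
                 gene_symbol = "G", transcript_id = "TX",
                 cds_position = 60L, cds_ref = substr(cdsr, 60, 60),
                 cds_alt = paste0(substr(cdsr, 60, 60), ins))
      ctx <- build_inframe_context(vv, c(TX = cdsr))
      if (!is.null(ctx)) {
        expect_equal(nchar(ctx$mutant_sequence) - nchar(translate_cds(cdsr)),
                     k)
      }
    }
  })
})

test_that("window counts match the documented boundary cases", {
  with_seed(46, prot <- random_protein(41))
  # interior missense with >= 10 residues flanking: 8+9+10+11 = 38 windows
  ctx <- neoforge:::new_context(prot, 21L, 21L, "residues",
                                source_type = "snv", gene_label = "G",
                                variant_key = "k")
  expect_equal(nrow(enumerate_peptides(ctx)), 38L)
  # missense at position 1: one window per length
  ctx1 <- neoforge:::new_context(prot, 1L, 1L, "residues",
                                 source_type = "snv", gene_label = "G",
                                 variant_key = "k")
  expect_equal(nrow(enumerate_peptides(ctx1)), 4L)
})

test_that("enumerated peptide sets equal the brute-force oracle", {
  with_seed(47, {
    for (i in 1:60) {
      n <- sample(12:60, 1)
      prot <- random_protein(n)
      a <- sample(n, 1)
      b <- min(n, a + sample(0:5, 1))
      joint <- sample(c(TRUE, FALSE), 1) && a < n
      ctx <- neoforge:::new_context(
        prot, a, if (joint) a else b, if (joint) "joint" else "residues",
        source_type = "frameshift", gene_label = "G", variant_key = "k")
      got <- enumerate_peptides(ctx)$sequence
      want <- brute_windows(prot, a, if (joint) a else b, joint = joint)
      expect_setequal(got, want)
      expect_true(all(nchar(got) >= 8 & nchar(got) <= 11))
    }
  })
})

test_that("missense peptides differ from wild-type in exactly one residue", {
  with_seed(48, {
    prot <- random_protein(50)
    p <- 25L
    old <- substr(prot, p, p)
    new <- sample(setdiff(aa20, old), 1)
    mut <- prot
    substr(mut, p, p) <- new
  })
  ctx <- neoforge:::new_context(mut, p, p, "residues",
                                wildtype_sequence = prot,
                                source_type = "snv", gene_label = "G",
                                variant_key = "k")
  peps <- enumerate_peptides(ctx)
  expect_true(all(!is.na(peps$wildtype_counterpart)))
  ndiff <- mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, peps$sequence, peps$wildtype_counterpart)
  expect_true(all(ndiff == 1L))
})

test_that("fusion peptides straddle the junction and count correctly", {
  with_seed(49, {
    part5 <- neoforge:::random_cds(12)
    part3 <- neoforge:::random_cds(12)
  })
  f <- list(gene5 = "AA", gene3 = "BB", breakpoint5 = "c:1",
            breakpoint3 = "c:2", junction_cds = paste0(part5, part3),
            junction_offset = 36L)
  peps <- fusion_peptides(f)
  # clean codon boundary with >= 10 codons each side: 7+8+9+10 windows
  expect_equal(nrow(peps), 34L)
  aa5 <- translate_cds(part5)
  aa3 <- translate_cds(part3)
  # every peptide contains residues from both partners
  expect_true(all(vapply(peps$sequence, function(p) {
    hits5 <- regexpr(p, paste0(aa5, aa3), fixed = TRUE)
    start <- as.integer(hits5)
    start <= nchar(aa5) && start + nchar(p) - 1L > nchar(aa5)
  }, TRUE)))
  # stop codon before the junction suppresses everything
  f_stop <- f
  f_stop$junction_cds <- paste0(substr(part5, 1, 15), "TAA",
                                substr(part5, 19, 36), part3)
  expect_equal(nrow(fusion_peptides(f_stop)), 0L)
  # inconsistent offset is a hard error
  f_bad <- f
  f_bad$junction_offset <- 999L
  expect_error(fusion_peptides(f_bad), "inconsistent")
  # mid-codon junction: the chimeric codon counts for both partners
  f_mid <- f
  f_mid$junction_offset <- 35L
  peps_mid <- fusion_peptides(f_mid)
  expect_true(nrow(peps_mid) > 0)
  expect_true(all(peps_mid$length >= 8 & peps_mid$length <= 11))
})
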