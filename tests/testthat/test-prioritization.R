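# Frozen high-precision reference values (30-digit arithmetic, computed
# independently of the implementation):
#   1/(1 + exp(-10)) = 0.999954602131297565605495223767
#   tanh(1)          = 0.761594155955764888119458282605
L0_REF <- 0.999954602131297565605495223767
TANH1_REF <- 0.761594155955764888119458282605

test_that("logistic rank weight has its inflection at 2 and correct tails", {
  expect_equal(logistic_rank_weight(2), 0.5, tolerance = 1e-12)
  expect_lt(logistic_rank_weight(100), 1e-10)
  expect_equal(logistic_rank_weight(1e-12), L0_REF, tolerance = 1e-12)
  # strictly decreasing and bounded in (0,1)
  x <- seq(0.01, 30, by = 0.07)
  L <- logistic_rank_weight(x)
  expect_true(all(diff(L) < 0))
  expect_true(all(L > 0 & L < 1))
  expect_error(logistic_rank_weight(0), "> 0")
})

test_that("expression component is tanh-shaped, monotone and unit-aware", {
  expect_equal(expression_component(0), 0)
  expect_equal(expression_component(10, "TPM"), TANH1_REF,
               tolerance = 1e-12)
  expect_equal(expression_component(2, "FFPM"), TANH1_REF,
               tolerance = 1e-12)
  v <- seq(0, 100, by = 0.5)
  ec <- expression_component(v)
  expect_true(all(diff(ec) > 0))
  expect_true(all(ec >= 0 & ec < 1))
  expect_error(expression_component(-1), ">= 0")
})

test_that("expression gate boundaries follow the documented thresholds", {
  expect_false(expression_gate(0.99, "snv"))
  expect_true(expression_gate(1.0, "snv"))
  expect_true(expression_gate(2.51, "fusion"))   # retained exemplar FFPM
  expect_false(expression_gate(NA_real_, "snv"))
  expect_false(expression_gate(0.5, "fusion"))
})

test_that("clonality is VAF for variants and 1 for fusions", {
  expect_equal(clonality_component(0.25, "snv"), 0.25)
  expect_equal(clonality_component(NA, "fusion"), 1.0)
  expect_error(clonality_component(1.2, "snv"), "within")
})

test_that("self-similarity agrees with a naive per-sequence scan", {
  with_seed(61, {
    seqs <- setNames(vapply(1:30, function(i) random_peptide(80), ""),
                     paste0("p", 1:30))
  })
  db <- build_proteome(seqs)
  with_seed(62, {
    queries <- c(
      # half copied verbatim from the proteome
      vapply(1:250, function(i) {
        src <- sample(seqs, 1)
        s <- sample(nchar(src) - 8, 1)
        substr(src, s, s + sample(7:10, 1))
      }, ""),
      vapply(1:250, function(i) random_peptide(sample(8:11, 1)), ""))
  })
  got <- self_similarity(queries, db)
  naive <- vapply(queries, function(q) {
    any(vapply(seqs, function(s) grepl(q, s, fixed = TRUE), TRUE))
  }, TRUE, USE.NAMES = FALSE)
  expect_equal(got, naive)
  expect_true(all(got[1:250]))
})

test_that("foreignness and agretopicity behave per contract", {
  fc <- foreignness_component(1.0, 1.0)
  expect_equal(fc$agretopicity_index, 1.0)
  # no wild-type counterpart (fusion/frameshift): fully foreign
  fc2 <- foreignness_component(0.3, NA_real_)
  expect_equal(fc2$foreignness, 1.0)
  expect_true(is.na(fc2$agretopicity_index))
  # weakly-binding wild type barely dents foreignness
  fc3 <- foreignness_component(0.1, 50)
  expect_equal(fc3$agretopicity_index, 500)
  expect_equal(fc3$foreignness, 1.0, tolerance = 1e-9)
  # strongly-binding wild type halves it at most
  fc4 <- foreignness_component(0.1, 1e-9)
  expect_gte(fc4$foreignness, 0.5)
  expect_lt(fc4$foreignness, 0.51)
})

test_that("priority score is bounded, vetoed and monotone", {
  expect_equal(priority_score(0.9, 0.8, 0.7, 0.9, self_match = TRUE,
                              gate_pass = TRUE), 0)
  expect_equal(priority_score(0.9, 0.8, 0.7, 0.9, self_match = FALSE,
                              gate_pass = FALSE), 0)
  expect_equal(priority_score(1, 1, 1, 1, FALSE, TRUE), 100)
  # monotone in each component
  base <- c(L = 0.5, e = 0.5, c = 0.5, f = 0.75)
  s0 <- priority_score(base["L"], base["e"], base["c"], base["f"],
                       FALSE, TRUE)
  for (k in names(base)) {
    up <- base
    up[k] <- up[k] + 0.2
    s1 <- priority_score(up["L"], up["e"], up["c"], up["f"], FALSE, TRUE)
    expect_gt(s1, s0)
  }
  with_seed(63, {
    comp <- matrix(runif(400, 0.01, 1), ncol = 4)
  })
  s <- priority_score(comp[, 1], comp[, 2], comp[, 3], comp[, 4],
                      self_match = FALSE, gate_pass = TRUE)
  expect_true(all(s >= 0 & s <= 100))
})

test_that("scoring pipeline wires components together correctly", {
  db <- build_proteome(c(ref1 = "MKKPASSAAQWERTYIPQSD"))
  peptides <- data.table::data.table(
    sequence = c("KVAELVHFL", "KVAELVHFM", "MKKPASSA"),
    source_type = c("snv", "snv", "snv"),
    gene_label = c("GOOD", "GOOD", "SELF"),
    variant_key = c("k1", "k2", "k3"),
    window_start = 1L, length = c(9L, 9L, 8L),
    covers = "1-1",
    wildtype_counterpart = c("KVAELVHFA", "KVAELVHFA", NA))
  binding <- data.table::data.table(
    peptide = c("KVAELVHFL", "KVAELVHFM", "MKKPASSA", "KVAELVHFA"),
    allele = "HLA-A*02:01",
    rank_percent = c(0.2, 0.2, 0.1, 5.0))
  data.table::setattr(binding, "class",
                      c("neo_binding", class(binding)))
  gene_expr <- c(GOOD = 20, SELF = 40, LOW = 0.4)
  vafs <- c(k1 = 0.8, k2 = 0.2, k3 = 0.9)
  sc <- score_candidates(peptides, binding, "A*02:01", gene_expr,
                         vaf_by_variant = vafs, proteome = db,
                         sample = "T1")
  expect_equal(nrow(sc), 3L)
  # exact proteome substring is vetoed to zero
  expect_true(sc[peptide == "MKKPASSA", self_match])
  expect_equal(sc[peptide == "MKKPASSA", priority_score], 0)
  # higher VAF outranks identical candidate with lower VAF
  expect_gt(sc[peptide == "KVAELVHFL", priority_score],
            sc[peptide == "KVAELVHFM", priority_score])
  # agretopicity recorded for missense
  expect_equal(sc[peptide == "KVAELVHFL", agretopicity_index], 5 / 0.2)
  # a candidate with rank 2.5 never outranks one with rank 1.5,
  # all else equal
  peps2 <- peptides[1:2]
  peps2$sequence <- c("AAAAAAAAA", "CCCCCCCCC")
  peps2$wildtype_counterpart <- NA_character_
  peps2$variant_key <- "k1"
  bind2 <- data.table::data.table(
    peptide = c("AAAAAAAAA", "CCCCCCCCC"), allele = "HLA-A*02:01",
    rank_percent = c(2.5, 1.5))
  data.table::setattr(bind2, "class", c("neo_binding", class(bind2)))
  sc2 <- rank_candidates(score_candidates(peps2, bind2, "A*02:01",
                                          gene_expr,
                                          vaf_by_variant = vafs,
                                          proteome = db))
  expect_equal(sc2$peptide[1], "CCCCCCCCC")
  expect_lt(logistic_rank_weight(2.5), 0.5)
})

test_that("ranking is deterministic with documented tie-breaking", {
  dt <- data.table::data.table(
    sample = "s", source_type = "snv", gene_label = "g",
    peptide = c("BBB", "AAA", "CCC", "DDD"),
    length = 9L, hla_allele = "HLA-A*02:01",
    rank_percent = c(0.3, 0.1, 0.3, 0.3),
    rank_percent_wt = NA_real_, agretopicity_index = NA_real_,
    expression_value = c(5, 5, 9, 5), expression_unit = "TPM",
    clonality = 1, logistic_weight = 0.9, expression_component = 0.5,
    foreignness = 1, self_match = FALSE, binder_class = "strong",
    priority_score = c(20, 80, 20, 20))
  ranked <- rank_candidates(dt)
  expect_equal(ranked$peptide, c("AAA", "CCC", "BBB", "DDD"))
  # permutation invariance
  with_seed(64, perm <- sample(nrow(dt)))
  expect_equal(rank_candidates(dt[perm]), ranked)
})
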