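make_depth <- function(contig, pos, depth) {
  dt <- data.table::data.table(contig = contig, pos = as.integer(pos),
                               depth = as.integer(depth))
  data.table::setkeyv(dt, c("contig", "pos"))
  data.table::setattr(dt, "class", c("neo_depth", class(dt)))
  dt[]
}

make_variants <- function(...) {
  dt <- data.table::data.table(...)
  defaults <- list(chrom = "chr1", filter = "PASS", tumor_depth = 30,
                   vaf = 0.5)
  for (nm in names(defaults)) {
    if (!nm %in% names(dt)) dt[, (nm) := defaults[[nm]]]
  }
  data.table::setattr(dt, "class", c("neo_variants", class(dt)))
  dt[]
}

test_that("compute_callable keeps exactly the CDS bases reaching min_depth", {
  cds <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000))
  dep <- make_depth("chr1", 1:1000, c(rep(12L, 600), rep(5L, 400)))
  ct <- compute_callable(dep, cds, 10L)
  expect_equal(ct$total_bases, 600L)
  expect_equal(ct$total_megabases, 600 / 1e6)
  # min_depth 1 with everything covered recovers the full CDS
  ct1 <- compute_callable(dep, cds, 1L)
  expect_equal(ct1$total_bases, 1000L)
  expect_error(compute_callable(dep, GenomicRanges::GRanges(), 10L), "empty")
})

test_that("callable set equals a brute-force per-position check", {
  with_seed(21, {
    pos <- sort(sample(1:5000, 1500))
    dep_val <- rpois(1500, 12)
  })
  dep <- make_depth("chr1", pos, dep_val)
  cds <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(100, 2000, 4000),
                                                         c(1500, 2600, 4500)))
  for (min_depth in c(1L, 10L, 20L)) {
    ct <- compute_callable(dep, cds, min_depth)
    # oracle: per-position membership test over the raw table
    lookup <- setNames(dep_val, pos)
    cds_pos <- unlist(lapply(seq_along(cds), function(i) {
      GenomicRanges::start(cds)[i]:GenomicRanges::end(cds)[i]
    }))
    oracle <- cds_pos[!is.na(lookup[as.character(cds_pos)]) &
                        lookup[as.character(cds_pos)] >= min_depth]
    got <- unlist(lapply(seq_along(ct$intervals), function(i) {
      GenomicRanges::start(ct$intervals)[i]:GenomicRanges::end(ct$intervals)[i]
    }))
    expect_equal(sort(got), sort(unname(oracle)))
  }
  # monotone non-increasing in min_depth
  sizes <- vapply(c(1L, 5L, 10L, 15L, 25L), function(md) {
    compute_callable(dep, cds, md)$total_bases
  }, 1)
  expect_true(all(diff(sizes) <= 0))
})

test_that("TMB eligibility follows filter, depth, territory and class", {
  cds <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 2000))
  dep <- make_depth("chr1", 1:1000, rep(30L, 1000))  # callable: 1..1000
  ct <- compute_callable(dep, cds, 10L)
  v <- make_variants(
    pos = c(100L, 200L, 300L, 400L, 500L, 1500L),
    ref = "A", alt = "G",
    consequence = c("missense", "synonymous", "stop_gain", "missense",
                    "missense", "missense"),
    filter = c("PASS", "PASS", "PASS", "germline", "PASS", "PASS"),
    tumor_depth = c(30, 30, 30, 30, 9, 30)
  )
  expect_equal(is_tmb_eligible(v, ct),
               c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE))
  # stop-gain counts for TMB but not for the epitope path
  expect_false("stop_gain" %in% select_epitope_variants(v)$consequence)
})

test_that("TMB arithmetic and invariances", {
  territory <- structure(
    list(intervals = GenomicRanges::GRanges("chr1",
                                            IRanges::IRanges(1, 1500000)),
         total_bases = 1500000L, total_megabases = 1.5, min_depth = 10L),
    class = "neo_callable")
  v <- make_variants(pos = c(10L, 20L, 30L), ref = "A", alt = "G",
                     consequence = "missense")
  rep <- compute_tmb(v, territory)
  expect_equal(rep$tmb, 2.0)
  # adding synonymous or non-PASS variants leaves TMB unchanged
  v2 <- rbind(v, make_variants(pos = c(40L, 50L), ref = "C", alt = "T",
                               consequence = c("synonymous", "missense"),
                               filter = c("PASS", "weak_evidence")))
  data.table::setattr(v2, "class", class(v))
  expect_equal(compute_tmb(v2, territory)$tmb, 2.0)
  # zero callable territory is a hard error
  empty <- structure(list(intervals = GenomicRanges::GRanges(),
                          total_bases = 0L, total_megabases = 0,
                          min_depth = 10L), class = "neo_callable")
  expect_error(compute_tmb(v, empty), "unusable")
})

test_that("Ti/Tv matches brute-force classification and handles edge cases", {
  v <- make_variants(pos = 1:6 * 10L,
                     ref = c("A", "G", "C", "T", "A", "C"),
                     alt = c("G", "A", "T", "C", "C", "A"),
                     consequence = "missense")
  expect_equal(titv_ratio(v), 4 / 2)
  # restriction to regions drops outside SNVs
  inside <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 55))
  expect_equal(titv_ratio(v, regions = inside), 4 / 1)
  # zero transversions -> undefined, not Inf
  ti_only <- make_variants(pos = c(10L, 20L), ref = "A", alt = "G",
                           consequence = "missense")
  expect_true(is.na(titv_ratio(ti_only)))
  # 200 random SNVs against a per-variant oracle
  with_seed(31, {
    ref <- sample(c("A", "C", "G", "T"), 200, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r),
                                          1), "")
  })
  vr <- make_variants(pos = seq_len(200) * 3L, ref = ref, alt = unname(alt),
                      consequence = "missense")
  is_ti <- paste0(ref, alt) %in% c("AG", "GA", "CT", "TC")
  expect_equal(titv_ratio(vr), sum(is_ti) / sum(!is_ti))
})

test_that("breadth of coverage is bounded and monotone in the threshold", {
  dep <- make_depth("chr1", 1:400, rep(c(5L, 15L, 25L, 35L), each = 100))
  target <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 400))
  b <- vapply(c(1, 10, 20, 30, 40), function(th) {
    breadth_of_coverage(dep, target, th)
  }, 1)
  expect_equal(b, c(1, 0.75, 0.5, 0.25, 0))
  expect_true(all(b >= 0 & b <= 1))
  expect_true(all(diff(b) <= 0))
})
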