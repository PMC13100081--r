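# Shared seeded toy cohort, generated once per test run. Seed 42 is the
# fixed "stated world" of the suite; tests assert against the generator's
# ground-truth manifest, never against values observed post hoc.

.toy_cache <- new.env(parent = emptyenv())

toy_cohort <- function() {
  if (is.null(.toy_cache$cohort)) {
    dir <- file.path(tempdir(), "neoforge-toy-cohort")
    .toy_cache$cohort <- simulate_cohort(toy_cohort_spec(seed = 42L), dir)
    .toy_cache$dir <- dir
  }
  .toy_cache$cohort
}

toy_pipeline <- function() {
  if (is.null(.toy_cache$pipeline)) {
    cohort <- toy_cohort()
    out_dir <- file.path(tempdir(), "neoforge-toy-out")
    .toy_cache$pipeline <- suppressMessages(
      run_pipeline(cohort$manifest_path, neo_config(), out_dir))
  }
  .toy_cache$pipeline
}

gt_value <- function(gt, s, m) gt[sample == s & metric == m, value]

# deterministic RNG wrapper for property-style loops
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

random_peptide <- function(n = 9L) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
               n, replace = TRUE), collapse = "")
}

# Minimal hand-written VCF used by the io tests.
write_mini_vcf <- function(path, rows) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=100000>",
    "##FILTER=<ID=PASS,Description=\"ok\">",
    "##FILTER=<ID=germline,Description=\"g\">",
    "##FILTER=<ID=weak_evidence,Description=\"w\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"AD\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"DP\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tNORMAL\tTUMOR")
  writeLines(c(hdr, rows), path)
  path
}
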