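# Independent brute-force oracles shared by the unit and acceptance suites.

aa20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")

random_protein <- function(n) paste(sample(aa20, n, replace = TRUE),
                                    collapse = "")

# Naive enumeration of every 8-11-mer window intersecting the altered span
# (or straddling a joint), the way one would do it on paper.
brute_windows <- function(seq, span_start, span_end, lengths = 8:11,
                          joint = FALSE) {
  n <- nchar(seq)
  out <- character(0)
  for (L in lengths) {
    if (n < L) next
    for (s in 1:(n - L + 1)) {
      e <- s + L - 1
      hit <- if (joint) s <= span_start && e >= span_start + 1
      else s <= span_end && e >= span_start
      if (hit) out <- c(out, substr(seq, s, e))
    }
  }
  unique(out[!grepl("[X*]", out)])
}
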