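#' @import data.table
#' @importFrom methods is
#' @importFrom stats setNames median uniroot na.omit rnorm runif rlnorm
#' @importFrom utils head tail
NULL

# Classed conditions so callers (and the CLI) can distinguish input/validation
# errors from internal stage failures.
neo_stop <- function(msg, class = "neo_input_error", ...) {
  stop(structure(
    class = c(class, "neo_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

neo_log <- function(fmt, ..., verbose = getOption("neoforge.verbose", FALSE)) {
  if (isTRUE(verbose)) message(sprintf(fmt, ...))
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x >= 0 && x == trunc(x)

assert_file <- function(path, what = "file") {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    neo_stop(sprintf("%s not found: %s", what, paste(path, collapse = ", ")))
  }
  invisible(path)
}

assert_cols <- function(dt, cols, what) {
  missing <- setdiff(cols, names(dt))
  if (length(missing)) {
    neo_stop(sprintf("%s is missing mandatory column(s): %s",
                     what, paste(missing, collapse = ", ")))
  }
  invisible(dt)
}

# Fixed-precision float rendering used by every table writer so that repeated
# runs are byte-identical.
fmt_num <- function(x, digits = 6L) {
  out <- ifelse(is.na(x), "NA", formatC(x, format = "f", digits = digits))
  # avoid "-0.000000"
  sub("^-(0\\.0+)$", "\\1", out)
}

write_tsv_deterministic <- function(dt, path, num_cols = NULL, digits = 6L) {
  dt <- data.table::as.data.table(dt)
  if (is.null(num_cols)) num_cols <- names(dt)[vapply(dt, is.double, TRUE)]
  out <- data.table::copy(dt)
  for (cc in intersect(num_cols, names(out))) {
    data.table::set(out, j = cc, value = fmt_num(out[[cc]], digits))
  }
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "NA",
                     eol = "\n")
  invisible(path)
}
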