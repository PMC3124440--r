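#' @import data.table
#' @importFrom methods as is
NULL

# Classed conditions so the command-line wrapper can map errors to exit codes.
abort_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("snvmine_config_error", "error")))
}
abort_missing_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("snvmine_missing_input", "error")))
}
abort_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("snvmine_format_error", "error")))
}

# Decompose a decimal threshold (as printed, e.g. 0.80 or 0.67) into an exact
# integer numerator/denominator so frequency comparisons against integer read
# counts are free of floating-point boundary artifacts (2/3 vs 0.67 must
# compare as 200/300 < 201/300).
decimal_fraction <- function(x) {
  stopifnot(length(x) == 1L, is.finite(x))
  s <- format(x, digits = 12, scientific = FALSE)
  if (!grepl("\\.", s)) {
    return(c(num = as.numeric(s), den = 1))
  }
  dec <- sub("^[^.]*\\.", "", s)
  dec <- sub("0+$", "", dec)
  den <- 10^nchar(dec)
  c(num = round(x * den), den = den)
}

# count/total < threshold, exactly
frac_lt <- function(count, total, threshold) {
  f <- decimal_fraction(threshold)
  count * f[["den"]] < f[["num"]] * total
}

# value <= threshold where value = 100 * count / total (a percentage), exactly
pct_le <- function(count, total, threshold_pct) {
  f <- decimal_fraction(threshold_pct)
  count * 100 * f[["den"]] <= f[["num"]] * total
}

`%||%` <- function(a, b) if (is.null(a)) b else a

phred_chars_to_int <- function(s, offset = 33L) {
  if (!nzchar(s)) return(integer(0))
  utf8ToInt(s) - offset
}

phred_int_to_chars <- function(q, offset = 33L) {
  if (!length(q)) return("")
  intToUtf8(as.integer(q) + offset)
}
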