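#' @keywords internal
"_PACKAGE"

# Derive a reproducible sub-seed for a named pipeline stage from one global
# seed. Keeps culling, effects, clustering etc. on independent streams while
# staying inside the 32-bit integer range set.seed() accepts.
sub_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 7919 + h * 104729) %% .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stop with a message listing the columns a table is missing.
check_columns <- function(tbl, cols, what = "table") {
  absent <- setdiff(cols, names(tbl))
  if (length(absent) > 0) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(absent, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

# Safe division: NA where the denominator is missing, zero or non-finite.
safe_div <- function(num, den) {
  out <- num / den
  out[!is.finite(out) | is.na(den) | den == 0] <- NA_real_
  out
}
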