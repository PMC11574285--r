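# Internal helpers shared across modules.

# Schema errors always name the offending column so adapters for real
# exports fail loudly and specifically.
abort_missing_column <- function(col, what = "table") {
  stop(sprintf("missing required column in %s: %s", what, col), call. = FALSE)
}

assert_columns <- function(df, cols, what = "table") {
  for (col in cols) {
    if (!col %in% names(df)) abort_missing_column(col, what)
  }
  invisible(df)
}

# Derive a component sub-seed from the root seed; kept below 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% (.Machine$integer.max - 1L)) + 1L
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}
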