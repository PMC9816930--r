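`%||%` <- function(x, y) if (is.null(x)) y else x

stop_fp <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

assert_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0L) {
    stop_fp("%s: missing required column(s): %s", what,
            paste(miss, collapse = ", "))
  }
  invisible(df)
}

# numeric column check with row numbers in the error
assert_nonneg_finite <- function(x, col, what) {
  x <- as.numeric(x)
  bad <- which(!is.finite(x) | x < 0)
  if (length(bad) > 0L) {
    stop_fp("%s: column '%s' must be finite and >= 0; offending row(s): %s",
            what, col, paste(utils::head(bad, 10L), collapse = ", "))
  }
  x
}

first_dups <- function(x) unique(x[duplicated(x)])

# read a CSV keeping key columns as character (codes may have leading zeros)
read_csv_keys <- function(path, chr_cols) {
  hdr <- names(read.csv(path, nrows = 1L, check.names = TRUE))
  keep <- intersect(chr_cols, hdr)
  read.csv(path, stringsAsFactors = FALSE,
           colClasses = setNames(rep("character", length(keep)), keep))
}
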