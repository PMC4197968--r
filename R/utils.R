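#' Stop with a formatted message
#' @noRd
abort_data <- function(...) stop(sprintf(...), call. = FALSE)

#' Assert that a tibble has the given columns
#' @noRd
check_columns <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort_data("%s is missing required column(s): %s", what,
               paste(missing, collapse = ", "))
  }
  invisible(df)
}

#' Occurrence counts of a numeric key vector
#' @noRd
table_counts <- function(key) {
  s <- sort(key)
  r <- rle(s)
  list(key = r$values, n = r$lengths)
}

#' Derive a stream-specific seed from a base seed
#'
#' Keeps derived seeds positive and below 2^31 so they are valid R seeds.
#' @noRd
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483587L) + 1L
}
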