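# Internal validation helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 allow_equal_lower = TRUE,
                                 allow_equal_upper = TRUE) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x))
    stop2(sprintf("'%s' must be a single finite number", name))
  lo_ok <- if (allow_equal_lower) x >= lower else x > lower
  hi_ok <- if (allow_equal_upper) x <= upper else x < upper
  if (!lo_ok || !hi_ok)
    stop2(sprintf("'%s' = %s is outside its valid range", name, format(x)))
  invisible(x)
}

assert_count <- function(x, name, minimum = 0L) {
  assert_scalar_number(x, name, lower = minimum)
  if (x != as.integer(x)) stop2(sprintf("'%s' must be an integer", name))
  invisible(as.integer(x))
}

assert_columns <- function(df, cols, what) {
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols))
    stop2(sprintf("%s is missing column(s): %s", what,
                  paste(missing_cols, collapse = ", ")))
  invisible(df)
}

#' Round half away from zero
#'
#' Report-layer rounding used for fold-enrichment and percentage figures,
#' where 3.25 rounds to 3.3 rather than banker's 3.2. Internal arithmetic is
#' never rounded; this is applied only when formatting results.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1).
#' @return Numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_away(3.25, 1)  # 3.3
round_half_away <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}
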