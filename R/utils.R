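#' Round half up
#'
#' Rounds to `digits` decimals with ties going away from zero, the convention
#' used for all presented chart and metric values. `base::round()` rounds
#' half to even, which disagrees with printed reference tables at exact
#' midpoints (e.g. 21.155 -> 21.16, not 21.15).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(21.155, 2) # 21.16
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # small tolerance absorbs binary representation error of decimal midpoints
  sign(x) * trunc(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Condition constructors. Each CLI exit code maps to one class:
#   sfh_config_error -> 2, sfh_io_error -> 3, sfh_join_error -> 4.
sfh_error <- function(class, message, ...) {
  stop(structure(
    class = c(class, "sfh_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

abort_config <- function(message, ...) sfh_error("sfh_config_error", message, ...)
abort_io     <- function(message, ...) sfh_error("sfh_io_error", message, ...)
abort_join   <- function(message, ...) sfh_error("sfh_join_error", message, ...)
abort_range  <- function(message, ...) sfh_error("sfh_range_error", message, ...)
abort_fit    <- function(message, ...) sfh_error("sfh_fit_error", message, ...)

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_config(sprintf("'%s' must be a single finite number", name))
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    abort_io(sprintf("%s is missing required column(s): %s",
                     what, paste(missing, collapse = ", ")))
  invisible(df)
}
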