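#' Construct a linear SFH growth chart
#'
#' A growth chart gives the expected symphysis-fundal height (SFH, cm) and a
#' lower/upper reference band as three straight lines in gestational week.
#' The constructor validates band ordering (`lower < expected < upper` at
#' every integer week of the chart's range) and requires all three slopes to
#' be strictly positive, since SFH increases through pregnancy.
#'
#' @param name short label for the chart.
#' @param expected_intercept,expected_slope coefficients of the expected-SFH
#'   line (cm, cm/week).
#' @param lower_intercept,lower_slope coefficients of the lower bound.
#' @param upper_intercept,upper_slope coefficients of the upper bound.
#' @param week_min,week_max integer gestational-week range over which the
#'   chart is valid; evaluation outside it is an error, not extrapolation.
#' @return an object of class `growth_chart`.
#' @seealso [basso_chart()] for the built-in default chart.
#' @export
growth_chart <- function(name,
                         expected_intercept, expected_slope,
                         lower_intercept, lower_slope,
                         upper_intercept, upper_slope,
                         week_min, week_max) {
  for (f in c("expected_intercept", "expected_slope", "lower_intercept",
              "lower_slope", "upper_intercept", "upper_slope",
              "week_min", "week_max"))
    stopifnot_scalar_number(get(f), f)
  if (week_min != as.integer(week_min) || week_max != as.integer(week_max))
    abort_config("week_min and week_max must be integers")
  if (week_min < 10 || week_max > 45 || week_min >= week_max)
    abort_config("week range must satisfy 10 <= week_min < week_max <= 45")
  if (expected_slope <= 0 || lower_slope <= 0 || upper_slope <= 0)
    abort_config("all chart slopes must be strictly positive")
  chart <- structure(
    list(name = as.character(name)[1],
         expected_intercept = expected_intercept,
         expected_slope = expected_slope,
         lower_intercept = lower_intercept, lower_slope = lower_slope,
         upper_intercept = upper_intercept, upper_slope = upper_slope,
         week_min = as.integer(week_min), week_max = as.integer(week_max)),
    class = "growth_chart")
  wk <- seq(chart$week_min, chart$week_max)
  lo <- lower_intercept + lower_slope * wk
  mid <- expected_intercept + expected_slope * wk
  hi <- upper_intercept + upper_slope * wk
  if (any(lo >= mid) || any(mid >= hi))
    abort_config(paste0(
      "invalid chart '", chart$name, "': band ordering lower < expected < ",
      "upper must hold at every integer week in [", week_min, ", ",
      week_max, "]"))
  chart
}

#' The Basso SFH reference chart for hyperglycemic pregnancy
#'
#' Default chart with expected line `1.082 + 0.966 * week`, lower bound
#' `0.629 + 0.95 * week` and upper bound `1.535 + 0.981 * week`, valid from
#' week 13 to week 42. The chart was derived from SFH measurements in
#' pregnancies complicated by type 2 diabetes, gestational diabetes and mild
#' gestational hyperglycemia under glycemic control.
#'
#' @return a `growth_chart`.
#' @export
#' @examples
#' tabulate_chart(basso_chart())[1:3, ]
basso_chart <- function() {
  growth_chart("basso",
               expected_intercept = 1.082, expected_slope = 0.966,
               lower_intercept = 0.629, lower_slope = 0.95,
               upper_intercept = 1.535, upper_slope = 0.981,
               week_min = 13, week_max = 42)
}

check_week_in_range <- function(chart, week) {
  if (any(week < chart$week_min | week > chart$week_max))
    abort_range(sprintf(
      "gestational week outside chart '%s' valid interval [%d, %d]",
      chart$name, chart$week_min, chart$week_max),
      week_min = chart$week_min, week_max = chart$week_max)
}

#' Expected SFH at a gestational week
#'
#' @param chart a [growth_chart()].
#' @param week gestational week(s); fractional values allowed, must lie
#'   within the chart range.
#' @return expected SFH in cm, unrounded.
#' @export
#' @examples
#' expected_fh(basso_chart(), 28)
expected_fh <- function(chart, week) {
  stopifnot(inherits(chart, "growth_chart"))
  check_week_in_range(chart, week)
  chart$expected_intercept + chart$expected_slope * week
}

#' Lower and upper chart bounds at a gestational week
#'
#' @inheritParams expected_fh
#' @return for scalar `week`, a named numeric `c(lower, upper)`; for a
#'   vector, a two-column matrix.
#' @export
chart_bounds <- function(chart, week) {
  stopifnot(inherits(chart, "growth_chart"))
  check_week_in_range(chart, week)
  lo <- chart$lower_intercept + chart$lower_slope * week
  hi <- chart$upper_intercept + chart$upper_slope * week
  if (length(week) == 1L) c(lower = lo, upper = hi)
  else cbind(lower = lo, upper = hi)
}

#' Tabulate a chart at integer weeks
#'
#' Evaluates the three chart lines at every integer week of the chart range
#' and rounds half-up to 2 decimals, the presentation convention of printed
#' SFH reference tables. Internal arithmetic elsewhere is never rounded.
#'
#' @param chart a [growth_chart()].
#' @return a data frame of class `chart_table` with columns
#'   `week`, `expected`, `lower`, `upper`.
#' @export
tabulate_chart <- function(chart) {
  stopifnot(inherits(chart, "growth_chart"))
  week <- seq(chart$week_min, chart$week_max)
  tab <- data.frame(
    week = week,
    expected = round_half_up(expected_fh(chart, week), 2),
    lower = round_half_up(chart$lower_intercept + chart$lower_slope * week, 2),
    upper = round_half_up(chart$upper_intercept + chart$upper_slope * week, 2))
  class(tab) <- c("chart_table", "data.frame")
  tab
}

#' Fit a linear growth chart to (week, SFH) observations
#'
#' The expected line is the ordinary least-squares fit of SFH on week. The
#' band is placed empirically: residuals from that fit are taken at their
#' `(1 - coverage)/2` and `1 - (1 - coverage)/2` quantiles, each observation's
#' fitted value is shifted by the corresponding quantile, and the bound lines
#' are re-fitted by least squares through the shifted values. Because the
#' shifted values lie exactly on a line, the bounds come out parallel to the
#' expected line, matching the near-parallel bands of published SFH charts.
#'
#' @param weeks gestational weeks of the observations.
#' @param sfh SFH measurements in cm, same length as `weeks`.
#' @param coverage target fraction of observations inside the band,
#'   in (0.5, 1). Default 0.95.
#' @param name label for the returned chart.
#' @return a `growth_chart` whose week range is the observed integer span.
#' @export
#' @examples
#' wk <- rep(13:42, each = 3)
#' fit_chart(wk, 1.082 + 0.966 * wk + rnorm(length(wk), sd = 0.47))
fit_chart <- function(weeks, sfh, coverage = 0.95, name = "fitted") {
  if (length(weeks) != length(sfh))
    abort_config("weeks and sfh must have the same length")
  keep <- is.finite(weeks) & is.finite(sfh)
  weeks <- weeks[keep]; sfh <- sfh[keep]
  if (length(weeks) < 10)
    abort_config("at least 10 (week, sfh) pairs are required")
  if (length(unique(round(weeks))) < 3)
    abort_fit("degenerate design: fewer than 3 distinct weeks represented")
  if (coverage <= 0.5 || coverage >= 1)
    abort_config("coverage must lie in (0.5, 1)")

  fit <- stats::lm(sfh ~ weeks)
  beta <- stats::coef(fit)
  if (beta[2] <= 0)
    abort_fit(sprintf(
      "fit failure: non-positive fitted slope %.4f (intercept %.4f, n = %d)",
      beta[2], beta[1], length(weeks)))
  res <- stats::residuals(fit)
  alpha <- (1 - coverage) / 2
  q <- stats::quantile(res, c(alpha, 1 - alpha), names = FALSE)
  # degenerate residual spread (e.g. noiseless input) gets a hair-width band
  # so the band-ordering invariant still holds
  eps <- 1e-9
  if (q[1] > -eps) q[1] <- -eps
  if (q[2] < eps) q[2] <- eps
  fitted_vals <- stats::fitted(fit)
  lo_fit <- stats::lm((fitted_vals + q[1]) ~ weeks)
  hi_fit <- stats::lm((fitted_vals + q[2]) ~ weeks)
  lo <- stats::coef(lo_fit); hi <- stats::coef(hi_fit)

  growth_chart(name,
               expected_intercept = unname(beta[1]),
               expected_slope = unname(beta[2]),
               lower_intercept = unname(lo[1]), lower_slope = unname(lo[2]),
               upper_intercept = unname(hi[1]), upper_slope = unname(hi[2]),
               week_min = floor(min(weeks)), week_max = ceiling(max(weeks)))
}

#' @export
print.growth_chart <- function(x, ...) {
  cat(sprintf("SFH growth chart '%s' (weeks %d-%d)\n",
              x$name, x$week_min, x$week_max))
  cat(sprintf("  expected: FH = %.4g + %.4g * week\n",
              x$expected_intercept, x$expected_slope))
  cat(sprintf("  lower:    FH = %.4g + %.4g * week\n",
              x$lower_intercept, x$lower_slope))
  cat(sprintf("  upper:    FH = %.4g + %.4g * week\n",
              x$upper_intercept, x$upper_slope))
  invisible(x)
}

#' Plot a chart, optionally overlaying measurements
#'
#' @param x a `growth_chart`.
#' @param measurements optional data frame with columns `week` and `sfh_cm`
#'   to overlay as points.
#' @param ... passed to [graphics::plot()].
#' @export
plot.growth_chart <- function(x, measurements = NULL, ...) {
  wk <- seq(x$week_min, x$week_max)
  hi <- x$upper_intercept + x$upper_slope * wk
  lo <- x$lower_intercept + x$lower_slope * wk
  graphics::plot(wk, expected_fh(x, wk), type = "l",
                 xlab = "gestational week", ylab = "SFH (cm)",
                 ylim = range(lo, hi,
                              if (!is.null(measurements)) measurements$sfh_cm),
                 main = x$name, ...)
  graphics::lines(wk, lo, lty = 2)
  graphics::lines(wk, hi, lty = 2)
  if (!is.null(measurements))
    graphics::points(measurements$week, measurements$sfh_cm,
                     pch = 16, cex = 0.5, col = "grey40")
  invisible(x)
}

#' Read or write a chart as JSON
#'
#' Charts serialize to a flat JSON object with the seven coefficient fields
#' plus the week range, so they can be passed between runs and tools.
#'
#' @param chart a `growth_chart`.
#' @param path file path.
#' @return `read_chart` returns a `growth_chart`; `write_chart` returns
#'   `path` invisibly.
#' @export
write_chart <- function(chart, path) {
  stopifnot(inherits(chart, "growth_chart"))
  jsonlite::write_json(unclass(chart), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_chart
#' @export
read_chart <- function(path) {
  if (!file.exists(path))
    abort_io(sprintf("chart file not found: %s", path))
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(growth_chart, x[c("name",
                            "expected_intercept", "expected_slope",
                            "lower_intercept", "lower_slope",
                            "upper_intercept", "upper_slope",
                            "week_min", "week_max")])
}

#' Export a chart table as CSV
#'
#' Writes the table produced by [tabulate_chart()] with header
#' `week,expected,lower,upper`.
#'
#' @param table a `chart_table`.
#' @param path output CSV path.
#' @export
write_chart_table <- function(table, path) {
  stopifnot(inherits(table, "chart_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
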