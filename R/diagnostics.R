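#' Build a 2x2 contingency table of predicted vs gold-standard class
#'
#' Binarizes the three-class SGA/AGA/LGA partition against one target class:
#' a subject is "positive" when labelled with the target class, negative
#' otherwise. Counts are predicted-vs-gold: `tp` (both positive), `fp`
#' (predicted positive, gold negative), `fn`, `tn`.
#'
#' @param predictions data frame with `subject_id` and `predicted`, e.g.
#'   from [predict_cohort()]; or a bare vector of predicted classes.
#' @param gold data frame with `subject_id` and `gold_class`; or a bare
#'   vector aligned with `predictions`.
#' @param target the positive class, `"SGA"` or `"LGA"`.
#' @return object of class `contingency_2x2` with fields `tp`, `fp`, `fn`,
#'   `tn`, `target`.
#' @export
build_table <- function(predictions, gold, target = c("SGA", "LGA")) {
  target <- match.arg(target)
  if (is.data.frame(predictions) || is.data.frame(gold)) {
    require_columns(predictions, c("subject_id", "predicted"), "predictions")
    require_columns(gold, c("subject_id", "gold_class"), "gold labels")
    only_pred <- setdiff(predictions$subject_id, gold$subject_id)
    only_gold <- setdiff(gold$subject_id, predictions$subject_id)
    if (length(only_pred) || length(only_gold))
      abort_join(sprintf(
        "subjects present in one input only: %s",
        paste(utils::head(c(only_pred, only_gold), 10), collapse = ", ")),
        only_predictions = only_pred, only_gold = only_gold)
    if (anyDuplicated(predictions$subject_id) || anyDuplicated(gold$subject_id))
      abort_join("each subject must appear exactly once in each input")
    m <- match(predictions$subject_id, gold$subject_id)
    pred <- as.character(predictions$predicted)
    truth <- as.character(gold$gold_class)[m]
  } else {
    if (length(predictions) != length(gold))
      abort_join("prediction and gold vectors have different lengths")
    pred <- as.character(predictions)
    truth <- as.character(gold)
  }
  pp <- pred == target
  gp <- truth == target
  contingency_2x2(tp = sum(pp & gp), fp = sum(pp & !gp),
                  fn = sum(!pp & gp), tn = sum(!pp & !gp),
                  target = target)
}

#' @rdname build_table
#' @param tp,fp,fn,tn nonnegative integer counts.
#' @export
contingency_2x2 <- function(tp, fp, fn, tn, target = "positive") {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts)))
    abort_config("contingency counts must be nonnegative integers")
  if (sum(counts) == 0)
    abort_config("contingency table total must be positive")
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn),
                 target = target),
            class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(predicted = c(x$target, paste0("not-", x$target)),
                              gold = c(x$target, paste0("not-", x$target))))
  print(m)
  invisible(x)
}

#' Wilson score confidence interval for a binomial proportion
#'
#' Returns the Wilson score interval (without continuity correction) on the
#' 0-100 percent scale. The Wilson interval is well behaved at proportions
#' of 0 and 1, where the Wald interval degenerates, which matters here
#' because perfect sensitivity (x = n) is a routine outcome in screening
#' validation.
#'
#' @param x numerator (successes).
#' @param n denominator (trials), at least 1.
#' @param level confidence level, default 0.95.
#' @return named numeric `c(low, high)` in percent, unrounded.
#' @export
#' @examples
#' round_half_up(wilson_interval(13, 13), 1) # c(77.2, 100.0)
wilson_interval <- function(x, n, level = 0.95) {
  if (n < 1) abort_config("undefined metric: denominator is zero")
  if (x < 0 || x > n) abort_config("numerator must lie in [0, denominator]")
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  100 * c(low = max(0, centre - half), high = min(1, centre + half))
}

metric_with_ci <- function(x, n, level) {
  if (is.na(n) || n == 0)
    return(structure(list(estimate = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, numerator = x, denominator = n,
                          level = level), class = "metric_ci"))
  ci <- wilson_interval(x, n, level)
  structure(list(estimate = 100 * x / n,
                 ci_low = unname(ci[1]), ci_high = unname(ci[2]),
                 numerator = as.integer(x), denominator = as.integer(n),
                 level = level),
            class = "metric_ci")
}

#' @export
format.metric_ci <- function(x, ...) {
  if (is.na(x$estimate)) return("undefined")
  sprintf("%.1f (%.1f; %.1f)",
          round_half_up(x$estimate, 1),
          round_half_up(x$ci_low, 1), round_half_up(x$ci_high, 1))
}

#' Diagnostic accuracy report from a 2x2 table
#'
#' Computes sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive and
#' negative predictive values `tp/(tp+fp)` and `tn/(tn+fn)`, and accuracy
#' `(tp+tn)/total`, each with a Wilson score interval at `level`. Metrics
#' with a zero denominator are reported as undefined (`NA`), never as 0 or
#' 100; the remaining metrics are still computed. Estimates are stored at
#' full precision; printing rounds half-up to 1 decimal on the percent
#' scale.
#'
#' @param table a [contingency_2x2()].
#' @param level confidence level, default 0.95.
#' @return object of class `diagnostic_report` with fields `target`,
#'   `table` and one `metric_ci` per metric.
#' @export
#' @examples
#' diagnostic_report(contingency_2x2(13, 20, 0, 173, target = "SGA"))
diagnostic_report <- function(table, level = 0.95) {
  stopifnot(inherits(table, "contingency_2x2"))
  with(table, structure(list(
    target = target,
    table = table,
    sensitivity = metric_with_ci(tp, tp + fn, level),
    specificity = metric_with_ci(tn, tn + fp, level),
    ppv = metric_with_ci(tp, tp + fp, level),
    npv = metric_with_ci(tn, tn + fn, level),
    accuracy = metric_with_ci(tp + tn, tp + fp + fn + tn, level)),
    class = "diagnostic_report"))
}

#' @export
print.diagnostic_report <- function(x, ...) {
  cat(format_report(x), sep = "\n")
  invisible(x)
}

#' Render a diagnostic report as a text table
#'
#' @param x a `diagnostic_report`.
#' @return character vector of lines mirroring a published
#'   Sens/Spec/PPV/NPV/Accuracy layout.
#' @export
format_report <- function(x) {
  stopifnot(inherits(x, "diagnostic_report"))
  c(sprintf("Diagnostic performance, target class %s (n = %d)", x$target,
            x$table$tp + x$table$fp + x$table$fn + x$table$tn),
    sprintf("  %-12s %s", "Sens", format(x$sensitivity)),
    sprintf("  %-12s %s", "Spec", format(x$specificity)),
    sprintf("  %-12s %s", "PPV", format(x$ppv)),
    sprintf("  %-12s %s", "NPV", format(x$npv)),
    sprintf("  %-12s %s", "Accuracy", format(x$accuracy)))
}

#' Export a diagnostic report as JSON
#'
#' Writes both full-precision values and the rounded presentation fields.
#'
#' @param x a `diagnostic_report`.
#' @param path output path.
#' @export
write_report <- function(x, path) {
  stopifnot(inherits(x, "diagnostic_report"))
  metr <- function(m) list(
    estimate = m$estimate, ci_low = m$ci_low, ci_high = m$ci_high,
    numerator = m$numerator, denominator = m$denominator, level = m$level,
    presentation = format(m))
  out <- list(
    target = x$target,
    table = unclass(x$table),
    metrics = lapply(x[c("sensitivity", "specificity", "ppv", "npv",
                         "accuracy")], metr))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' McNemar's paired comparison of two classifiers
#'
#' Compares two charts (or rules) applied to the same subjects through their
#' per-subject correctness. The statistic is computed from discordant pairs:
#' `b` subjects classified correctly by A but not B, `c` the reverse;
#' `(b - c)^2 / (b + c)` without continuity correction, or
#' `(|b - c| - 1)^2 / (b + c)` with it (the correction is skipped when
#' `b == c`, where it would inflate an exactly null statistic); the p-value
#' comes from a chi-square distribution with 1 degree of freedom. With no
#' discordant pairs the statistic is 0 and p is 1.
#'
#' @param correct_a,correct_b logical vectors, per-subject correctness of
#'   the two classifiers over the same subjects in the same order.
#' @param correction apply the continuity correction? Default `FALSE`.
#' @return object of class `mcnemar_result` with `discordant_b`,
#'   `discordant_c`, `statistic`, `p_value`, `correction`.
#' @export
mcnemar_compare <- function(correct_a, correct_b, correction = FALSE) {
  if (length(correct_a) != length(correct_b))
    abort_join("paired correctness vectors have different lengths")
  b <- sum(correct_a & !correct_b)
  c_ <- sum(!correct_a & correct_b)
  if (b + c_ == 0) {
    stat <- 0; p <- 1
  } else {
    # the continuity correction only applies when the discordant counts
    # differ; with b == c it would turn an exactly null statistic into
    # 1/(b+c), so it is skipped there (the convention of mcnemar.test)
    stat <- if (correction && b != c_) (abs(b - c_) - 1)^2 / (b + c_)
            else (b - c_)^2 / (b + c_)
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  structure(list(discordant_b = as.integer(b), discordant_c = as.integer(c_),
                 statistic = stat, p_value = p, correction = correction),
            class = "mcnemar_result")
}

#' @export
print.mcnemar_result <- function(x, ...) {
  cat(sprintf("McNemar's test: X2 = %.4g, p = %.4g (b = %d, c = %d%s)\n",
              x$statistic, x$p_value, x$discordant_b, x$discordant_c,
              if (x$correction) ", continuity-corrected" else ""))
  invisible(x)
}
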