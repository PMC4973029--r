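SIZE_CLASSES <- c("SGA", "AGA", "LGA")

#' Classify a single SFH measurement against a chart
#'
#' A measurement below the chart's lower bound predicts a small-for-
#' gestational-age newborn (SGA), above the upper bound a large-for-
#' gestational-age newborn (LGA), and anything in between (bounds included)
#' is appropriate for gestational age (AGA). Strict inequalities mirror the
#' "< P10 / > P90" reading of birth-weight percentile classes.
#'
#' @param chart a [growth_chart()].
#' @param week gestational week(s) within the chart range.
#' @param sfh SFH measurement(s) in cm.
#' @return character vector of `"SGA"`, `"AGA"` or `"LGA"`.
#' @export
#' @examples
#' classify_measure(basso_chart(), 13, c(12.5, 13.64, 14.5))
classify_measure <- function(chart, week, sfh) {
  stopifnot(inherits(chart, "growth_chart"))
  check_week_in_range(chart, week)
  lo <- chart$lower_intercept + chart$lower_slope * week
  hi <- chart$upper_intercept + chart$upper_slope * week
  ifelse(sfh < lo, "SGA", ifelse(sfh > hi, "LGA", "AGA"))
}

# distance past the violated bound; 0 for in-band points
violation_margin <- function(chart, week, sfh) {
  lo <- chart$lower_intercept + chart$lower_slope * week
  hi <- chart$upper_intercept + chart$upper_slope * week
  pmax(0, lo - sfh, sfh - hi)
}

#' Predict a pregnancy's size class from its SFH record
#'
#' Reduces a subject's longitudinal SFH measurements to one predicted class
#' using a measure-selection rule:
#' \describe{
#'   \item{`"last"`}{(default) the final measurement inside the chart range
#'     decides — the convention of validating against the last measure taken
#'     at birth.}
#'   \item{`"worst"`}{the in-range measurement farthest outside the band
#'     decides; ties go to the later week.}
#'   \item{`"first-abnormal"`}{the earliest in-range measurement outside the
#'     band decides; if none violates, the last measure (AGA) decides.}
#' }
#'
#' @param chart a [growth_chart()].
#' @param weeks gestational weeks of one subject's measurements.
#' @param sfh corresponding SFH values in cm.
#' @param rule measure-selection rule.
#' @param subject_id identifier used in error messages and the result.
#' @return a list with `subject_id`, `predicted`, `deciding_week`,
#'   `deciding_sfh` and `margin` (cm past the violated bound; 0 in-band).
#' @export
predict_subject <- function(chart, weeks, sfh, rule = c("last", "worst", "first-abnormal"),
                            subject_id = NA_character_) {
  rule <- match.arg(rule)
  stopifnot(inherits(chart, "growth_chart"), length(weeks) == length(sfh))
  weeks <- unname(weeks); sfh <- unname(sfh)
  ord <- order(weeks)
  weeks <- weeks[ord]; sfh <- sfh[ord]
  in_range <- weeks >= chart$week_min & weeks <= chart$week_max
  if (!any(in_range))
    abort_range(sprintf(
      "subject '%s' has no measurement inside chart range [%d, %d]",
      subject_id, chart$week_min, chart$week_max), subject_id = subject_id)
  weeks <- weeks[in_range]; sfh <- sfh[in_range]
  margins <- violation_margin(chart, weeks, sfh)
  i <- switch(rule,
    "last" = length(weeks),
    "worst" = {
      # max margin; ties resolved toward the later week
      which(margins == max(margins))[sum(margins == max(margins))]
    },
    "first-abnormal" = if (any(margins > 0)) which(margins > 0)[1] else length(weeks))
  list(subject_id = subject_id,
       predicted = classify_measure(chart, weeks[i], sfh[i]),
       deciding_week = weeks[i],
       deciding_sfh = sfh[i],
       margin = margins[i])
}

#' Predict size classes for a whole cohort
#'
#' Applies [predict_subject()] to every subject in a long-format measurement
#' table.
#'
#' @param chart a [growth_chart()].
#' @param measurements data frame with columns `subject_id`, `week`,
#'   `sfh_cm`, one row per antenatal visit.
#' @param rule measure-selection rule, see [predict_subject()].
#' @return data frame with one row per subject: `subject_id`, `predicted`,
#'   `deciding_week`, `deciding_sfh`, `margin`.
#' @export
predict_cohort <- function(chart, measurements, rule = "last") {
  require_columns(measurements, c("subject_id", "week", "sfh_cm"),
                  "measurements table")
  validate_measurements(measurements)
  rows <- lapply(split(measurements, measurements$subject_id), function(d) {
    as.data.frame(predict_subject(chart, d$week, d$sfh_cm, rule = rule,
                                  subject_id = as.character(d$subject_id[1])),
                  stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

validate_measurements <- function(measurements) {
  bad_sfh <- which(measurements$sfh_cm <= 5 | measurements$sfh_cm >= 60 |
                     !is.finite(measurements$sfh_cm))
  if (length(bad_sfh))
    abort_io(sprintf("SFH values outside (5, 60) cm at row(s): %s",
                     paste(utils::head(bad_sfh, 5), collapse = ", ")))
  bad_wk <- which(measurements$week < 10 | measurements$week > 45 |
                    !is.finite(measurements$week))
  if (length(bad_wk))
    abort_io(sprintf("gestational weeks outside [10, 45] at row(s): %s",
                     paste(utils::head(bad_wk, 5), collapse = ", ")))
  invisible(measurements)
}

#' Gold-standard size class from birth weight and a percentile table
#'
#' Classifies a newborn against a per-week birth-weight percentile reference
#' (such as the Lubchenco reference, supplied by the user as a table): below
#' the week's P10 entry is SGA, above its P90 entry is LGA, otherwise AGA
#' (values equal to a percentile entry are AGA). Fractional gestational ages
#' are truncated to completed weeks, the usual obstetric convention.
#'
#' @param birth_weight_g birth weight(s) in grams.
#' @param ga_at_birth gestational age(s) at birth in weeks (may be
#'   fractional).
#' @param percentile_table data frame with columns `week`, `p10_g`, `p90_g`.
#' @return character vector of `"SGA"`, `"AGA"` or `"LGA"`.
#' @export
#' @examples
#' tab <- data.frame(week = 38, p10_g = 2500, p90_g = 4000)
#' gold_class_from_weight(4100, 38.6, tab) # "LGA"
gold_class_from_weight <- function(birth_weight_g, ga_at_birth,
                                   percentile_table) {
  require_columns(percentile_table, c("week", "p10_g", "p90_g"),
                  "percentile table")
  wk <- floor(ga_at_birth)
  idx <- match(wk, percentile_table$week)
  if (anyNA(idx))
    abort_io(sprintf(
      "percentile table does not cover completed week(s): %s",
      paste(unique(wk[is.na(idx)]), collapse = ", ")))
  p10 <- percentile_table$p10_g[idx]
  p90 <- percentile_table$p90_g[idx]
  ifelse(birth_weight_g < p10, "SGA",
         ifelse(birth_weight_g > p90, "LGA", "AGA"))
}

#' Attach gold-standard classes to an outcomes table
#'
#' Uses the `gold_class` column when present and filled; otherwise derives
#' the class from `birth_weight_g` via [gold_class_from_weight()]. Directly
#' supplied labels win over derived ones.
#'
#' @param outcomes data frame with `subject_id`, `ga_at_birth_weeks` and
#'   either `gold_class` or `birth_weight_g`.
#' @param percentile_table optional percentile reference, required when any
#'   gold class must be derived from weight.
#' @return `outcomes` with a complete `gold_class` column.
#' @export
resolve_gold_class <- function(outcomes, percentile_table = NULL) {
  require_columns(outcomes, c("subject_id", "ga_at_birth_weeks"),
                  "outcomes table")
  gold <- if ("gold_class" %in% names(outcomes)) {
    g <- as.character(outcomes$gold_class)
    g[g == ""] <- NA_character_
    g
  } else rep(NA_character_, nrow(outcomes))
  need <- is.na(gold)
  if (any(need)) {
    if (!"birth_weight_g" %in% names(outcomes))
      abort_io("gold_class missing and no birth_weight_g column to derive it")
    if (is.null(percentile_table))
      abort_config("a percentile table is required to derive gold classes from birth weight")
    gold[need] <- gold_class_from_weight(outcomes$birth_weight_g[need],
                                         outcomes$ga_at_birth_weeks[need],
                                         percentile_table)
  }
  bad <- !gold %in% SIZE_CLASSES
  if (any(bad))
    abort_io(sprintf("invalid gold_class label(s): %s",
                     paste(unique(gold[bad]), collapse = ", ")))
  outcomes$gold_class <- gold
  outcomes
}
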