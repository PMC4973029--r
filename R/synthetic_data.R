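#' Configuration for a synthetic antenatal SFH cohort
#'
#' Defaults emulate the structure of a validation cohort of 206
#' hyperglycemic pregnancies: gold-standard prevalences of 6.3% SGA and
#' 13.6% LGA, 91.7% of deliveries at term (>= 37 weeks), a mean of 4.76 SFH
#' measures per subject taken between weeks 24 and 38 plus one final measure
#' at delivery, and SFH trajectories following the reference expected line
#' `1.082 + 0.966 * week` with independent Normal visit noise. SGA and LGA
#' fetuses get a constant trajectory shift (`offset_sga`, `offset_lga`);
#' with the defaults the shifts are large relative to the noise, so true
#' growth deviations essentially never escape detection while false
#' positives from the AGA noise tail remain possible.
#'
#' @param n_subjects number of pregnancies.
#' @param p_sga,p_lga gold-standard class prevalences.
#' @param p_term probability of delivery at >= 37 weeks.
#' @param visit_week_range integer week window for routine visits.
#' @param mean_visits expected measures per subject (shifted-Poisson count).
#' @param traj_intercept,traj_slope SFH trajectory coefficients (cm,
#'   cm/week).
#' @param noise_sd per-visit measurement noise SD in cm; the default 0.47
#'   makes the +/-1.96 SD spread (~1.84 cm) match the reference band width
#'   at mid-pregnancy.
#' @param offset_sga,offset_lga trajectory shifts in cm for SGA (< 0) and
#'   LGA (> 0) fetuses.
#' @param seed random seed; `NULL` leaves the RNG state alone.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 206,
                          p_sga = 0.063, p_lga = 0.136, p_term = 0.917,
                          visit_week_range = c(24, 38), mean_visits = 4.76,
                          traj_intercept = 1.082, traj_slope = 0.966,
                          noise_sd = 0.47,
                          offset_sga = -2.5, offset_lga = 2.5,
                          seed = NULL) {
  cfg <- list(n_subjects = n_subjects, p_sga = p_sga, p_lga = p_lga,
              p_term = p_term, visit_week_range = visit_week_range,
              mean_visits = mean_visits, traj_intercept = traj_intercept,
              traj_slope = traj_slope, noise_sd = noise_sd,
              offset_sga = offset_sga, offset_lga = offset_lga, seed = seed)
  if (n_subjects < 1 || n_subjects != round(n_subjects))
    abort_config("n_subjects must be a positive integer")
  if (p_sga < 0 || p_lga < 0 || p_sga + p_lga >= 1)
    abort_config("prevalences must be nonnegative with p_sga + p_lga < 1")
  if (p_term < 0 || p_term > 1) abort_config("p_term must lie in [0, 1]")
  if (noise_sd <= 0) abort_config("noise_sd must be positive")
  if (offset_sga >= 0 || offset_lga <= 0)
    abort_config("offsets must satisfy offset_sga < 0 < offset_lga")
  if (mean_visits < 1) abort_config("mean_visits must be at least 1")
  if (length(visit_week_range) != 2 ||
      visit_week_range[1] > visit_week_range[2])
    abort_config("visit_week_range must be an ordered pair of weeks")
  # preterm deliveries fall in 32-36; a visit window above every possible
  # delivery age would leave subjects unmeasurable
  if (visit_week_range[1] > 40)
    abort_config("visit window starts above all possible delivery ages")
  structure(cfg, class = "cohort_config")
}

#' Simulate a longitudinal SFH cohort with gold-standard outcomes
#'
#' Generates, per subject: a gold-standard class drawn from
#' `Categorical(p_sga, 1 - p_sga - p_lga, p_lga)`; a gestational age at
#' birth (term with probability `p_term`, uniform over integer weeks 37-40,
#' otherwise preterm uniform over 32-36); a shifted-Poisson number of
#' routine visits at distinct integer weeks within the visit window capped
#' at the delivery age, plus one final measure at the delivery week; and SFH
#' values `traj_intercept + traj_slope * week + class offset +
#' Normal(0, noise_sd)`, clamped to the physiologic (5, 60) cm range.
#' Identical config and seed yield an identical cohort.
#'
#' @param config a [cohort_config()].
#' @return list with `measurements` (columns `subject_id`, `week`,
#'   `sfh_cm`) and `outcomes` (columns `subject_id`, `ga_at_birth_weeks`,
#'   `gold_class`).
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_subjects = 20, seed = 1))
#' head(cohort$measurements)
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_subjects
  ids <- sprintf("S%04d", seq_len(n))
  gold <- sample(SIZE_CLASSES, n, replace = TRUE,
                 prob = c(config$p_sga, 1 - config$p_sga - config$p_lga,
                          config$p_lga))
  term <- stats::runif(n) < config$p_term
  ga <- ifelse(term, sample(37:40, n, replace = TRUE),
               sample(32:36, n, replace = TRUE))
  offset <- c(SGA = config$offset_sga, AGA = 0, LGA = config$offset_lga)[gold]

  meas <- vector("list", n)
  for (i in seq_len(n)) {
    n_visits <- 1L + stats::rpois(1, config$mean_visits - 1)
    candidates <- seq(config$visit_week_range[1],
                      min(config$visit_week_range[2], ga[i]))
    candidates <- setdiff(candidates, ga[i])
    k <- min(max(n_visits - 1L, 0L), length(candidates))
    weeks <- sort(c(if (k > 0) sample(candidates, k), ga[i]))
    sfh <- config$traj_intercept + config$traj_slope * weeks + offset[i] +
      stats::rnorm(length(weeks), sd = config$noise_sd)
    sfh <- pmin(pmax(sfh, 5 + 1e-6), 60 - 1e-6)
    meas[[i]] <- data.frame(subject_id = ids[i], week = weeks, sfh_cm = sfh)
  }
  list(measurements = do.call(rbind, c(meas, make.row.names = FALSE)),
       outcomes = data.frame(subject_id = ids, ga_at_birth_weeks = ga,
                             gold_class = unname(gold),
                             stringsAsFactors = FALSE))
}

#' Shift a chart's band for paired-comparison experiments
#'
#' Returns a copy of `chart` with the lower bound moved down and the upper
#' bound moved up by `band_shift` cm (negative values narrow the band).
#' Useful as a synthetic stand-in for a second, differently calibrated
#' reference chart when exercising paired McNemar comparisons; widening the
#' band can only lose true positives, so it yields a systematically less
#' sensitive chart.
#'
#' @param chart a [growth_chart()].
#' @param band_shift cm; 0 returns an identical chart.
#' @return a `growth_chart`.
#' @export
degrade_chart <- function(chart, band_shift) {
  stopifnot(inherits(chart, "growth_chart"))
  stopifnot_scalar_number(band_shift, "band_shift")
  growth_chart(paste0(chart$name, if (band_shift != 0)
                        sprintf("_shift%+g", band_shift) else ""),
               expected_intercept = chart$expected_intercept,
               expected_slope = chart$expected_slope,
               lower_intercept = chart$lower_intercept - band_shift,
               lower_slope = chart$lower_slope,
               upper_intercept = chart$upper_intercept + band_shift,
               upper_slope = chart$upper_slope,
               week_min = chart$week_min, week_max = chart$week_max)
}
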