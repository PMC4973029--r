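test_that("2x2 tables binarize the three-class partition against a target", {
  # published SGA configuration: 33 predicted positive, 13 gold positive,
  # no missed cases, 206 subjects
  d <- labels_for_counts(13, 20, 0, 173, target = "SGA")
  tab <- build_table(d[c("subject_id", "predicted")],
                     d[c("subject_id", "gold_class")], target = "SGA")
  expect_equal(unclass(tab)[c("tp", "fp", "fn", "tn")],
               list(tp = 13L, fp = 20L, fn = 0L, tn = 173L))
  # published LGA configuration
  d2 <- labels_for_counts(28, 17, 0, 161, target = "LGA")
  tab2 <- build_table(d2$predicted, d2$gold_class, target = "LGA")
  expect_equal(with(tab2, c(tp, fp, fn, tn)), c(28, 17, 0, 161))
  # perfect agreement has no off-diagonal counts
  tab3 <- build_table(c("SGA", "AGA", "LGA"), c("SGA", "AGA", "LGA"), "SGA")
  expect_equal(tab3$fp + tab3$fn, 0)
  # AGA and LGA both collapse to "not SGA"
  tab4 <- build_table(c("SGA", "LGA"), c("AGA", "AGA"), "SGA")
  expect_equal(with(tab4, c(tp, fp, fn, tn)), c(0, 1, 0, 1))
})

test_that("unmatched or duplicated subjects are join errors listing ids", {
  pred <- data.frame(subject_id = c("a", "b"), predicted = c("SGA", "AGA"))
  gold <- data.frame(subject_id = c("a", "zzz"), gold_class = c("SGA", "AGA"))
  expect_error(build_table(pred, gold, "SGA"), "zzz", class = "sfh_join_error")
  expect_error(build_table(c("SGA", "AGA"), "SGA", target = "SGA"),
               class = "sfh_join_error")
})

test_that("Wilson intervals reproduce the published confidence limits", {
  r1 <- round_half_up(wilson_interval(13, 13), 1)
  expect_equal(unname(r1), c(77.2, 100.0))
  expect_equal(unname(round_half_up(wilson_interval(173, 173), 1)),
               c(97.8, 100.0))
  expect_equal(unname(round_half_up(wilson_interval(186, 206), 1)),
               c(85.5, 93.6))
  expect_equal(unname(round_half_up(wilson_interval(189, 206), 1)),
               c(87.2, 94.8))
  expect_equal(unname(round_half_up(wilson_interval(13, 33), 1)),
               c(24.7, 56.3))
  expect_equal(unname(round_half_up(wilson_interval(28, 45), 1)),
               c(47.6, 74.9))
})

test_that("Wilson intervals agree with the score interval in prop.test", {
  set.seed(31)
  for (i in 1:200) {
    n <- sample(1:400, 1)
    x <- sample(0:n, 1)
    ours <- wilson_interval(x, n)
    ref <- suppressWarnings(
      100 * stats::prop.test(x, n, correct = FALSE)$conf.int)
    expect_equal(unname(ours), as.numeric(ref), tolerance = 1e-9)
  }
})

test_that("Wilson intervals contain the estimate, pin the boundaries, and tighten with n", {
  expect_equal(unname(wilson_interval(0, 25)[1]), 0)
  expect_equal(unname(round_half_up(wilson_interval(25, 25), 1)[2]), 100.0)
  set.seed(32)
  for (i in 1:50) {
    n <- sample(2:300, 1); x <- sample(0:n, 1)
    ci <- wilson_interval(x, n)
    expect_lte(ci[1], 100 * x / n + 1e-12)
    expect_gte(ci[2], 100 * x / n - 1e-12)
  }
  w1 <- diff(wilson_interval(10, 20))
  w2 <- diff(wilson_interval(100, 200))
  w3 <- diff(wilson_interval(1000, 2000))
  expect_true(w1 > w2 && w2 > w3)
  expect_error(wilson_interval(3, 0), class = "sfh_config_error")
})

test_that("diagnostic reports reproduce the published validation metrics", {
  sga <- diagnostic_report(contingency_2x2(13, 20, 0, 173, target = "SGA"))
  est <- function(m) round_half_up(m$estimate, 1)
  expect_equal(est(sga$sensitivity), 100.0)
  expect_equal(est(sga$specificity), 89.6)
  expect_equal(est(sga$ppv), 39.4)
  expect_equal(est(sga$npv), 100.0)
  expect_equal(est(sga$accuracy), 90.3)
  # the SGA specificity upper limit computes to 93.2 (173/193), not the
  # printed 95.2; the computed value is reported
  expect_equal(round_half_up(sga$specificity$ci_high, 1), 93.2)
  expect_equal(round_half_up(sga$specificity$ci_low, 1), 84.5)

  lga <- diagnostic_report(contingency_2x2(28, 17, 0, 161, target = "LGA"))
  expect_equal(est(lga$sensitivity), 100.0)
  expect_equal(est(lga$specificity), 90.4)
  expect_equal(est(lga$ppv), 62.2)
  expect_equal(est(lga$npv), 100.0)
  # 189/206 = 91.747..., half-up to 91.7
  expect_equal(est(lga$accuracy), 91.7)
  expect_equal(round_half_up(lga$sensitivity$ci_low, 1), 87.9)
  expect_equal(round_half_up(lga$npv$ci_low, 1), 97.7)
})

test_that("metrics equal direct count ratios on random tables", {
  set.seed(33)
  for (i in 1:200) {
    counts <- stats::rmultinom(1, size = sample(20:400, 1),
                               prob = c(0.1, 0.1, 0.05, 0.75))[, 1]
    tp <- counts[1]; fp <- counts[2]; fn <- counts[3]; tn <- counts[4]
    if (sum(counts) == 0) next
    rep_ <- diagnostic_report(contingency_2x2(tp, fp, fn, tn))
    if (tp + fn > 0) expect_equal(rep_$sensitivity$estimate, 100 * tp / (tp + fn))
    else expect_true(is.na(rep_$sensitivity$estimate))
    if (tn + fp > 0) expect_equal(rep_$specificity$estimate, 100 * tn / (tn + fp))
    if (tp + fp > 0) expect_equal(rep_$ppv$estimate, 100 * tp / (tp + fp))
    if (tn + fn > 0) expect_equal(rep_$npv$estimate, 100 * tn / (tn + fn))
    expect_equal(rep_$accuracy$estimate, 100 * (tp + tn) / sum(counts))
    # prevalence-weighted identity
    if (tp + fn > 0 && tn + fp > 0) {
      prev <- (tp + fn) / sum(counts)
      expect_equal(rep_$accuracy$estimate,
                   rep_$sensitivity$estimate * prev +
                     rep_$specificity$estimate * (1 - prev),
                   tolerance = 1e-9)
    }
  }
})

test_that("zero-denominator metrics are undefined, not 0 or 100", {
  r <- diagnostic_report(contingency_2x2(0, 5, 0, 95))
  expect_true(is.na(r$sensitivity$estimate))
  expect_equal(format(r$sensitivity), "undefined")
  expect_false(is.na(r$specificity$estimate))
  # an error-free table scores 100 everywhere
  perfect <- diagnostic_report(contingency_2x2(7, 0, 0, 93))
  expect_equal(perfect$sensitivity$estimate, 100)
  expect_equal(perfect$specificity$estimate, 100)
  expect_equal(perfect$accuracy$estimate, 100)
})

test_that("McNemar statistic follows the discordant-pair formula", {
  res0 <- mcnemar_compare(c(TRUE, FALSE), c(TRUE, FALSE))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
  # b = 5, c = 5: perfectly symmetric discordance
  a <- c(rep(TRUE, 5), rep(FALSE, 5))
  res1 <- mcnemar_compare(a, !a)
  expect_equal(res1$statistic, 0)
  expect_equal(res1$p_value, 1)
  # b = 10, c = 0
  res2 <- mcnemar_compare(rep(TRUE, 10), rep(FALSE, 10))
  expect_equal(res2$statistic, 10)
  expect_equal(res2$discordant_b, 10L)
  expect_error(mcnemar_compare(TRUE, c(TRUE, FALSE)), class = "sfh_join_error")
})

test_that("McNemar matches brute-force pair tallies and stats::mcnemar.test", {
  set.seed(34)
  for (i in 1:50) {
    n <- 50
    a <- runif(n) < 0.7
    b <- runif(n) < 0.6
    for (corr in c(FALSE, TRUE)) {
      ours <- mcnemar_compare(a, b, correction = corr)
      brute <- mcnemar_brute_force(a, b, correction = corr)
      expect_equal(ours$statistic, brute$statistic)
      expect_equal(ours$p_value, brute$p_value)
      if (ours$discordant_b + ours$discordant_c > 0) {
        ref <- stats::mcnemar.test(table(factor(a, c(TRUE, FALSE)),
                                         factor(b, c(TRUE, FALSE))),
                                   correct = corr)
        expect_equal(ours$statistic, unname(ref$statistic))
        expect_equal(ours$p_value, unname(ref$p.value))
      }
    }
  }
})

test_that("reports export to JSON with presentation strings", {
  dir <- withr::local_tempdir()
  r <- diagnostic_report(contingency_2x2(13, 20, 0, 173, target = "SGA"))
  p <- file.path(dir, "report.json")
  write_report(r, p)
  back <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(back$target, "SGA")
  expect_equal(back$metrics$sensitivity$presentation, "100.0 (77.2; 100.0)")
  expect_equal(back$metrics$accuracy$numerator, 186)
  lines <- format_report(r)
  expect_match(lines[2], "100.0 \\(77.2; 100.0\\)")
  expect_match(lines[6], "90.3 \\(85.5; 93.6\\)")
})
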