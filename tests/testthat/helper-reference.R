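# Published Basso chart tabulation, weeks 13-42: expected / lower / upper
# SFH in cm at 2 decimals. Used to pin tabulate_chart() cell by cell.
basso_reference_table <- function() {
  m <- matrix(c(
    13, 13.64, 12.98, 14.29,
    14, 14.61, 13.93, 15.27,
    15, 15.57, 14.88, 16.25,
    16, 16.54, 15.83, 17.23,
    17, 17.50, 16.78, 18.21,
    18, 18.47, 17.73, 19.19,
    19, 19.44, 18.68, 20.17,
    20, 20.40, 19.63, 21.16,
    21, 21.37, 20.58, 22.14,
    22, 22.33, 21.53, 23.12,
    23, 23.30, 22.48, 24.10,
    24, 24.27, 23.43, 25.08,
    25, 25.23, 24.38, 26.06,
    26, 26.20, 25.33, 27.04,
    27, 27.16, 26.28, 28.02,
    28, 28.13, 27.23, 29.00,
    29, 29.10, 28.18, 29.98,
    30, 30.06, 29.13, 30.97,
    31, 31.03, 30.08, 31.95,
    32, 31.99, 31.03, 32.93,
    33, 32.96, 31.98, 33.91,
    34, 33.93, 32.93, 34.89,
    35, 34.89, 33.88, 35.87,
    36, 35.86, 34.83, 36.85,
    37, 36.82, 35.78, 37.83,
    38, 37.79, 36.73, 38.81,
    39, 38.76, 37.68, 39.79,
    40, 39.72, 38.63, 40.78,
    41, 40.69, 39.58, 41.76,
    42, 41.65, 40.53, 42.74), ncol = 4, byrow = TRUE)
  data.frame(week = m[, 1], expected = m[, 2], lower = m[, 3], upper = m[, 4])
}

# Independent McNemar oracle: tally the paired 2x2 table explicitly and
# apply the textbook formula to its off-diagonal cells.
mcnemar_brute_force <- function(correct_a, correct_b, correction = FALSE) {
  tab <- matrix(0L, 2, 2)
  for (i in seq_along(correct_a)) {
    r <- if (correct_a[i]) 1L else 2L
    c_ <- if (correct_b[i]) 1L else 2L
    tab[r, c_] <- tab[r, c_] + 1L
  }
  b <- tab[1, 2]; c_ <- tab[2, 1]
  if (b + c_ == 0) return(list(statistic = 0, p_value = 1))
  stat <- if (correction && b != c_) (abs(b - c_) - 1)^2 / (b + c_)
          else (b - c_)^2 / (b + c_)
  list(statistic = stat, p_value = stats::pchisq(stat, 1, lower.tail = FALSE))
}

# Cohort-sized label vectors realizing a given predicted-vs-gold 2x2 table.
labels_for_counts <- function(tp, fp, fn, tn, target = "SGA") {
  other <- if (target == "SGA") "AGA" else "AGA"
  n <- tp + fp + fn + tn
  data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    predicted = c(rep(target, tp + fp), rep(other, fn + tn)),
    gold_class = c(rep(target, tp), rep(other, fp),
                   rep(target, fn), rep(other, tn)),
    stringsAsFactors = FALSE)
}
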