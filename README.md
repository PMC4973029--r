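# sfhchart

Symphysis-fundal height (SFH) growth charts and their diagnostic validation.

SFH — the tape-measured distance in centimetres from the pubic symphysis to
the uterine fundus — is, in much of the world, the primary antenatal proxy
for fetal growth. A reference SFH chart gives the expected SFH and a
lower/upper band as functions of gestational week; a pregnancy whose SFH
falls below the band flags a possible small-for-gestational-age (SGA)
newborn, above it a large-for-gestational-age (LGA) one. Before such a
chart is adopted in a clinic — particularly for high-risk groups such as
pregnancies complicated by diabetes or gestational hyperglycemia, which
tend to produce larger babies — its screening performance has to be
validated against a gold-standard classification of the newborns actually
delivered.

`sfhchart` is for perinatal epidemiologists and biostatisticians doing that
kind of chart construction and validation. It provides:

* **Chart model** — linear charts `FH = a + b·week` with linear lower/upper
  bounds, validated for band ordering; evaluation, integer-week tabulation
  (half-up rounding to 2 decimals), and fitting: the expected line by
  ordinary least squares, the band by shifting it to the empirical residual
  quantiles at `(1−coverage)/2` and `1−(1−coverage)/2`.
* **Classification** — per-pregnancy predicted SGA/AGA/LGA from
  longitudinal SFH records (by default the last in-range measure decides,
  the convention when the final measure is taken at birth), plus
  gold-standard assignment from birth weight against a per-week P10/P90
  percentile table (`< P10` → SGA, `> P90` → LGA).
* **Diagnostics** — 2×2 predicted-vs-gold tables; sensitivity, specificity,
  PPV, NPV and accuracy, each with a Wilson score 95% interval
  `(p̂ + z²/2n ± z√(p̂(1−p̂)/n + z²/4n²)) / (1 + z²/n)`; and McNemar's
  paired chi-square `(b−c)²/(b+c)` on the discordant pairs for comparing
  two charts on the same subjects.
* **Cohort simulation** — longitudinal cohorts with configurable class
  prevalences, term-delivery fraction, visit schedules and trajectory
  noise, so the full pipeline (fit → classify → validate → compare) runs
  end to end with no external data.
* **CLI** — `simulate`, `fit`, `tabulate`, `classify`, `validate` and
  `compare` verbs via `inst/cli/sfhchart.R`, reading and writing plain CSV
  and JSON.

## Worked example

The built-in default chart and its tabulation:

```r
library(sfhchart)
basso_chart()
#> SFH growth chart 'basso' (weeks 13-42)
#>   expected: FH = 1.082 + 0.966 * week
#>   lower:    FH = 0.629 + 0.95 * week
#>   upper:    FH = 1.535 + 0.981 * week
head(tabulate_chart(basso_chart()), 3)
#>   week expected lower upper
#> 1   13    13.64 12.98 14.29
#> 2   14    14.61 13.93 15.27
#> 3   15    15.57 14.88 16.25
```

Validation metrics from a 2×2 table of predicted vs gold-standard SGA
(13 true positives, 20 false positives, 0 false negatives, 173 true
negatives over 206 pregnancies):

```r
diagnostic_report(contingency_2x2(13, 20, 0, 173, target = "SGA"))
#> Diagnostic performance, target class SGA (n = 206)
#>   Sens         100.0 (77.2; 100.0)
#>   Spec         89.6 (84.5; 93.2)
#>   PPV          39.4 (24.7; 56.3)
#>   NPV          100.0 (97.8; 100.0)
#>   Accuracy     90.3 (85.5; 93.6)
```

Sensitivity of 100% with a wide interval (13/13 positives caught), about
four in ten screen-positives confirmed SGA (PPV 39.4%), and nine in ten
subjects classified correctly overall (accuracy 90.3%).

The same pipeline end to end on a simulated cohort, then a paired
comparison against a deliberately widened (less sensitive) chart:

```r
cohort <- simulate_cohort(cohort_config(seed = 1))   # 206 pregnancies
reports <- cmd_validate(cohort$measurements, cohort$outcomes)
reports$LGA
#> Diagnostic performance, target class LGA (n = 206)
#>   Sens         100.0 (87.5; 100.0)
#>   Spec         96.1 (92.1; 98.1)
#>   PPV          79.4 (63.2; 89.7)
#>   NPV          100.0 (97.8; 100.0)
#>   Accuracy     96.6 (93.2; 98.3)

cmp <- cmd_compare(cohort$measurements, cohort$outcomes,
                   basso_chart(), degrade_chart(basso_chart(), 2))
cmp$LGA$mcnemar
#> McNemar's test: X2 = 10.12, p = 0.001463 (b = 25, c = 7)
```

The widened chart loses 25 subjects the default chart got right while
fixing only 7, a significant degradation on the discordant pairs.

Or from a shell:

```sh
Rscript inst/cli/sfhchart.R simulate --out cohort --seed 1
Rscript inst/cli/sfhchart.R validate --measurements cohort/measurements.csv \
    --outcomes cohort/outcomes.csv --out reports
```

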