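---
title: "SFH chart construction, classification and diagnostic validation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SFH chart construction, classification and diagnostic validation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfhchart)
```

This vignette documents the statistical model behind `sfhchart`, the
conventions the implementation commits to, the design of the synthetic
cohort generator, and what the package's tests do and do not establish
about real data.

## The chart model

A symphysis-fundal height (SFH) reference chart is represented as three
straight lines in gestational week $w$:

$$\widehat{FH}(w) = a + b\,w, \qquad L(w) = a_L + b_L\,w, \qquad
U(w) = a_U + b_U\,w,$$

with all slopes strictly positive (SFH grows through pregnancy) and the
band ordering $L(w) < \widehat{FH}(w) < U(w)$ enforced at every integer
week of the chart's validity range. The built-in default chart
(`basso_chart()`) uses $a = 1.082$, $b = 0.966$, $a_L = 0.629$,
$b_L = 0.95$, $a_U = 1.535$, $b_U = 0.981$ over weeks 13–42; it was
derived for pregnancies complicated by type 2 diabetes, gestational
diabetes and mild gestational hyperglycemia, a population that tends
toward larger fetuses and is poorly served by general-population charts.

Evaluation accepts fractional weeks — gestational age is continuous — but
the chart range is a hard boundary: asking for week 12 or 43 of a 13–42
chart raises an error rather than extrapolating, because a screening
decision outside the calibrated range has no support.

Whether a published band of this form is a confidence interval of the mean
or a reference (percentile) band is often ambiguous in the source
material. The package does not take a position: `fit_chart()` exposes a
`coverage` parameter, and the band it fits is an empirical reference band
containing a `coverage` fraction of the observations, which is the reading
that makes a band usable for classifying individuals. Either
interpretation of a printed chart can be reproduced by choosing `coverage`
accordingly.

### Fitting

`fit_chart()` estimates the expected line by ordinary least squares of SFH
on week. The band is placed empirically: with residuals $r_i$ and target
coverage $\gamma$, the bounds shift the fitted values by the
$(1-\gamma)/2$ and $1-(1-\gamma)/2$ empirical residual quantiles, and each
bound line is then re-fitted by least squares through the shifted values.
Since the shifted values lie exactly on a line, this re-fit returns the
expected slope with a shifted intercept — the bounds are parallel to the
expected line. That is a deliberate simplification: it is the simplest
scheme consistent with the near-parallel bands of published linear SFH
charts, it needs no distributional assumption on the residuals, and its
empirical coverage is correct by construction at the fitted data. It does
not model variance that changes with gestational age; a chart whose band
genuinely widens with week needs a different (e.g. quantile-regression)
band model, which is out of scope.

Degenerate inputs are handled explicitly: fewer than 3 distinct weeks is a
design error (a line plus band cannot be identified), a non-positive
fitted slope is a fit failure reported with diagnostics rather than a
silently invalid chart, and noiseless input — where both residual
quantiles are zero — receives a hair-width band ($\pm 10^{-9}$ cm) so the
ordering invariant survives.

### Tabulation and rounding

`tabulate_chart()` evaluates the lines at integer weeks and rounds
**half-up** to 2 decimals, because published reference tables round ties
away from zero (e.g. an upper bound of 21.155 cm prints as 21.16).
`round_half_up()` implements this with a tolerance absorbing binary
floating-point representation error, since 21.155 is stored as
21.15499…; `base::round()`'s half-to-even rule would disagree with
printed tables at exact midpoints. Rounding is applied only at
presentation; every internal computation is unrounded. Reported
percentages round half-up to 1 decimal on the percent scale.

## Classification

A measurement classifies as SGA below $L(w)$, LGA above $U(w)$, AGA
otherwise. Values **exactly on a bound are AGA**: the strict inequalities
mirror the "$< P10$ / $> P90$" definition of birth-weight percentile
classes. A pregnancy's longitudinal record reduces to one prediction via a
measure-selection rule:

* `"last"` (default): the final in-range measurement decides. This is the
  validation convention when the last measure is taken at birth, and it
  makes the prediction invariant both to earlier measurements' values and
  to anything after the deciding measure.
* `"worst"`: the measurement farthest outside the band decides (ties to
  the later week) — a sensitivity analysis for "ever flagged, how badly".
* `"first-abnormal"`: the earliest in-range band violation decides, the
  natural reading of a per-visit screen that refers a pregnancy the first
  time it crosses a bound; with no violation the last measure (AGA)
  decides. A per-visit rule cannot return more than one class per
  pregnancy, so this is the package's one-class rendering of it.

Each prediction carries a `margin`: the distance in cm past the violated
bound (0 inside the band), useful for asking how borderline a call was.

Gold-standard classes come either directly (a `gold_class` column, which
wins when both sources are present) or from birth weight against a
per-week P10/P90 percentile table, with fractional gestational ages
truncated to completed weeks — the standard obstetric lookup convention.
The percentile reference itself (e.g. the classical Lubchenco table) is
deliberately **not** bundled: it is licensed reference data the user
supplies; `inst/extdata/` ships only a clearly labelled synthetic stand-in
for examples and tests.

## Diagnostics

Predicted-vs-gold 2×2 tables binarize the three-class partition against
one target class at a time (SGA-vs-rest, LGA-vs-rest). From a table
$(tp, fp, fn, tn)$ the report computes Sens $= tp/(tp+fn)$, Spec
$= tn/(tn+fp)$, PPV $= tp/(tp+fp)$, NPV $= tn/(tn+fn)$ and accuracy
$= (tp+tn)/n$. A metric with a zero denominator is reported as undefined
(`NA`), never as 0 or 100, while the others are still computed.

Intervals are **Wilson score without continuity correction**. The choice
matters: perfect sensitivity ($x = n$) is routine in screening validation,
the Wald interval collapses there, and the Wilson interval remains
informative (13/13 gives 77.2–100.0 at 95%). Tests cross-check the
implementation against the score interval in `stats::prop.test(correct =
FALSE)` over random $(x, n)$.

Two charts applied to the same subjects are compared with McNemar's test
on per-subject correctness: $b$ subjects chart A got right and B wrong,
$c$ the reverse, statistic $(b-c)^2/(b+c)$, $p$ from $\chi^2_1$. The
continuity correction $(|b-c|-1)^2/(b+c)$ is available behind a flag
(default off) and is skipped when $b = c$, where it would inflate an
exactly null statistic to $1/(b+c)$ — the same convention as
`stats::mcnemar.test`, which serves as the independent oracle in the test
suite. With $b + c = 0$ the statistic is 0 and $p = 1$.

## The synthetic cohort generator

`simulate_cohort()` exists so the full pipeline is testable end to end
with no data download. Its defaults emulate a validation cohort of 206
hyperglycemic pregnancies: gold prevalences 6.3% SGA and 13.6% LGA, 91.7%
term deliveries, and a mean of 4.76 SFH measures per subject between weeks
24 and 38 plus one final measure at the delivery week. Per subject:

* gold class $\sim$ Categorical$(p_{SGA},\, 1-p_{SGA}-p_{LGA},\, p_{LGA})$;
* gestational age at birth: term (uniform integer 37–40) with probability
  `p_term`, otherwise preterm uniform on 32–36 — the source cohort reports
  only the term fraction, so the within-stratum distributions are the
  package's own choice of plausible integer ranges;
* visit count $1 + \text{Poisson}(\bar v - 1)$ at distinct integer weeks
  in the visit window capped at delivery, plus the delivery-week measure;
* SFH $= 1.082 + 0.966\,w + \delta_{class} + \varepsilon$,
  $\varepsilon \sim N(0, \sigma)$, clamped to the physiologic (5, 60) cm
  range.

Two generative parameters are the package's own calibration, fixed once:

* $\sigma = 0.47$ cm, so that the $\pm 1.96\sigma$ spread ($\approx$ 1.84
  cm) matches the default chart's band width at mid-pregnancy — AGA
  trajectories then exceed the band with the small tail probability a
  band of that width implies (roughly 1–2.5% per side, week-dependent);
* $\delta_{SGA} = -2.5$ cm, $\delta_{LGA} = +2.5$ cm, about five noise
  SDs, so true growth deviations essentially never escape detection at
  the deciding measure while false positives from the AGA noise tail
  remain possible — reproducing the fn $= 0$, fp $> 0$ pattern a
  well-calibrated chart shows on its target population.

What the generator does **not** emulate: between-pregnancy biological
heterogeneity (every AGA fetus follows the same mean line, so realized
false-positive counts are lower than in real cohorts, where maternal and
fetal variation widens the AGA spread), within-subject correlation of
measurement error (visit noise is independent; a future hook), real
antenatal visit calendars, and any dependence of SFH on maternal BMI or
glycemic trajectory. Passing end-to-end tests therefore demonstrates that
the pipeline's machinery is correct under a known generative model — not
that any chart achieves these operating characteristics on real
pregnancies.

`degrade_chart()` widens (or narrows) a chart's band by a constant, giving
a synthetic stand-in for a second, differently calibrated chart in paired
comparisons: a widened band can only lose true positives, so it yields a
systematically less sensitive comparator with known direction.

## Problem sizes and determinism

The test suite and the acceptance script use problem sizes chosen to make
Monte-Carlo assertions stable at comfortable margins: chart-fit recovery
and band coverage at $n = 2000$ pairs (recovered slope within $\pm 0.02$,
intercept within $\pm 0.5$, coverage in 93–97%), generator convergence
checks at $n = 5000$ subjects within 3 Monte-Carlo SDs, oracle-equivalence
sweeps of 200 random cases, and 100 replicate cohorts of 206 for the
no-false-negative rate. All randomness flows through explicit seeds:
identical config plus seed reproduces a byte-identical cohort, which the
file-level tests assert by hashing.

## Known limitations

* Linear charts only; LMS/GAMLSS-style nonlinear references and
  age-varying band widths are out of scope.
* The band-fitting recipe yields parallel bounds by construction.
* One gold standard per analysis; no adjudication between weight-derived
  and directly supplied labels beyond "direct wins".
* The simulator's independence assumptions understate real false-positive
  rates (see above); simulation-based operating characteristics should be
  read as machinery checks, not clinical estimates.
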