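---
title: "Methods: urinalysis progress-bar scoring and two-segment ARIMA forecasting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: urinalysis progress-bar scoring and two-segment ARIMA forecasting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uaprogress)
```

## The scoring model

`uaprogress` operationalizes a progress-bar view of adherence in mandatory
substance-use treatment programs that monitor patients by scheduled
urinalysis. Each test occasion has a trinary outcome and a score:

* negative test: **+1**
* positive test: **−1**
* missed (scheduled but not taken) test: **0**

Per patient, the cumulative sum of these scores over test occasions is the
*progress bar*: a monotonically rising curve reflects sustained abstinence,
a drop marks a relapse, and a plateau marks missed appointments. By
construction consecutive values differ by at most one.

At the group level, for program week $i$,

$$\mathrm{score}_i = \sum_{\text{tests in week } i} s_t, \qquad
  \text{adjusted score}_i = \mathrm{score}_i / n_i,$$

where $n_i$ counts the urinalyses actually *taken* in week $i$. A missed
test contributes 0 to the numerator and is excluded from the denominator: a
missed appointment is not a taken urinalysis, so it should neither dilute
nor inflate the attendance-standardized score. The adjusted score lies in
$[-1, 1]$: $+1$ means every tested patient that week was negative, $-1$
that every tested patient was positive. It is stored as an exact double
division and compared in tests at $10^{-12}$ absolute tolerance.

Weeks are **patient-relative**: week 1 is each patient's first program
week, and group aggregation aligns patients on program week, not calendar
date. A 52-week group curve only makes sense if all patients share the
program-week axis; calendar alignment would smear protocol structure (the
biweekly testing parity, the mid-program phase change) across enrolment
dates. Whether to align on enrolment was genuinely open; patient-relative
alignment is this package's choice.

## Cohort filters and the descriptive summary

The study-flow filters mirror a typical retrospective cohort construction:

* **Engagement** — patients with fewer than 4 attended occasions are
  excluded (too little data for a time-series contribution). An
  "outpatient visit" is operationalized as an attended test occasion,
  since visits and urinalyses are coupled in this protocol; users whose
  visit data are separate can pre-filter their own way.
* **Recency** — patients whose last attended occasion precedes the study
  end by more than 26 weeks are excluded; such gaps are usually
  confounded (e.g. re-arrest restarting treatment). A patient with no
  attended occasion has no "most recent visit" and is excluded by
  convention.
* **Completion** — at least one attended occasion in each program half and
  a last attended occasion within 26 weeks of the program end. No formal
  completer definition exists beyond a flowchart, so this operationalization
  is declared, not inherited.

All filters conserve patients (input = retained + excluded) and are
idempotent. The descriptive summary reports each logical attribute as a
count and a one-decimal percentage of the denominator, rounded **half away
from zero** (the convention of clinical descriptive tables; base R's
`round()` rounds half to even), and each numeric attribute as mean and SD.

## The protocol simulator

No patient-level dataset accompanies the scoring method, so the package
ships a first-class generator that emulates the treatment protocol as a
per-patient state machine:

* testing every 2 weeks in the **high-demand** phase, starting at week 2;
* **stabilization** after 4 negative samples accumulated since the last
  positive, switching the patient to **monthly** (modeled as every 4 weeks
  on the integer week grid) **low-demand** testing;
* a positive result in either phase returns the patient to biweekly
  testing and resets the stabilization count (a full restart — the
  minimal reading consistent with "return to biweekly testing"; the
  threshold is configurable);
* a missed appointment leaves phase and count unchanged but delays the
  next test by exactly 1 week — the minimal mechanism that reproduces the
  observed drift of tests from even onto odd program weeks over time
  (configurable via `miss_delay`);
* per-occasion Bernoulli dropout with no re-entry.

Stochastic settings default to the study conditions: 312 patients over 52
weeks, `p_missed = 0.15`, `p_positive_low = 0.15`,
`p_dropout_per_occasion = 0.01`, and `p_positive_high = 0.4`, chosen once
so that the mean transition week into low demand, among patients who reach
it within the program, sits near the protocol's 6-month milestone
(~23 weeks under these defaults; an exact 26-week truncated mean would
require implausibly high relapse rates inside a 52-week window). A master
seed drives per-patient substreams derived deterministically, so cohorts
are reproducible and a patient's trajectory does not depend on cohort
size or ordering.

What the generator does **not** emulate: covariate-dependent relapse
risk, pharmacological dynamics, judicial interruptions (long absences are
handled by the recency filter, not simulated mechanistically), or any
effect of the concurrent group-psychotherapy schedule on testing. Passing
tests on simulated cohorts therefore demonstrate correctness of the
scoring and analysis machinery under protocol-shaped data, not clinical
validity on real cohorts.

## The time-series stage

The adjusted weekly score is analyzed as two segments split at week 27 —
the program's nominal midpoint and the approximate average entry into low
demand — giving 26 points per segment for a 52-week program. Weeks in
which nobody tested have an undefined adjusted score; the default policy
fills them with 0 (the neutral midpoint between an all-negative and an
all-positive week, fabricating no trend), linear interpolation being
available as an option. A constant filled series aborts the analysis with
a degenerate-series error.

Per segment the pipeline runs:

1. **Augmented Dickey-Fuller test** for a unit root, regression with
   constant and linear trend, `floor((T-1)^(1/3))` augmentation lags by
   default. The tau statistic's p-value is interpolated from the published
   Dickey-Fuller critical-value table for the trend case (Fuller 1976;
   Banerjee et al. 1993) and clamped to the table's `[0.01, 0.99]` range.
   Rejection indicates stationarity.
2. **Order choice** — either fixed `(p, d, q)` orders supplied by the
   caller, or a grid search: `d` is the smallest order in `0..max_d`
   whose differenced series rejects a unit root, then `(p, q)` minimizes
   AIC over the grid, ties broken toward fewer lag coefficients
   (`p + q`), then smaller `p`. No selection procedure is canonical here;
   AIC over an ADF-anchored grid is this package's documented choice.
3. **Maximum-likelihood ARIMA fit** via `stats::arima` (method `"ML"`,
   fixed optimizer settings, so repeated fits on identical input are
   identical). A mean term is included only for `d = 0`. Fitting orders
   such as `(3,4,7)` on a 26-point segment is supported but triggers a
   small-sample warning when the differenced sample has fewer than
   `3 (p + q + 1)` points — 22 points for 10 lag coefficients is an
   over-parameterized fit whose coefficients should not be interpreted.
4. **Box-Pierce portmanteau test** on the residuals,
   $Q = T \sum_{k=1}^{m} \hat\rho_k^2$ against $\chi^2_{m - (p+q)}$, with
   $m = \min(10, \lfloor T/5 \rfloor)$ raised to $p + q + 1$ when the
   order demands it. Box-Pierce is the named diagnostic here; the
   Ljung-Box variant, which corrects the small-sample distribution and is
   generally preferable at these segment lengths, is available via
   `type = "ljung-box"`. A large p-value (no detectable residual
   autocorrelation) supports using the fit for prediction; the report
   exposes the ADF, coefficient and Box-Pierce results separately and
   makes no single "fit for prediction" ruling.
5. **Forecasting** with normal-theory intervals; for integrated models
   interval width grows with horizon as forecast-error variance
   accumulates.

High-order example configurations such as `(3,4,7)` / `(2,2,3)` are
shipped as a documented example in the tests and CLI, not as defaults:
`d = 4` on 26 points is statistically extreme, and the package's defaults
(`max_p = max_q = 3`, `max_d = 2`, auto-selection) are the recommended
route.

## Numerical choices and degenerate inputs

* Adjusted scores: exact division, `NA` iff `n = 0`.
* Percentage rounding: half away from zero, one decimal.
* ADF: error on constant series (degenerate regression) and on series
  shorter than `lags + 10`.
* ARIMA: error when `length - d <= p + q + 1`; non-convergence raises an
  error carrying the optimizer message rather than returning a bogus fit.
* Order selection: candidates that fail to converge are skipped; if no
  differencing order passes the ADF gate, the selection errors rather
  than guessing.
* Significance threshold `alpha = 0.05` throughout, configurable.
* All simulation seeds are 32-bit integers; per-patient seeds are drawn
  from the master seed via `sample.int(.Machine$integer.max, n)`.

## Problem sizes in the test suite

The suite exercises the statistical properties at sizes chosen to keep a
full run near half a minute while leaving the Monte-Carlo margins wide:
1,000 random datasets for scoring-oracle equivalence; 100 replicates per
AR(1) coefficient (`n = 500`) for parameter recovery (observed mean
absolute error ~0.03 against a 0.08 bound); 1,000 white-noise series for
the Box-Pierce size check; 200 replicates each for ADF size and power;
simulated cohorts of 100-500 patients for the protocol invariants. The
acceptance script recomputes the same quantities from scratch at the same
sizes.

## Known limitations

* The ADF p-value is interpolated from an eight-point table and clamped
  to `[0.01, 0.99]`; it is a decision tool, not a precise tail
  probability.
* 26-point segments support only low-order ARIMA models with any
  statistical comfort; the high-order example configuration is
  reproducible machinery, not a recommendation.
* The simulator's drift mechanism (fixed 1-week delay per miss) is the
  simplest that produces even/odd parity mixing; real schedule drift is
  heterogeneous.
* Attributes for the descriptive summary are caller-supplied booleans; no
  diagnostic logic is implemented.
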