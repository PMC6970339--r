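# uaprogress

Scoring and forecasting toolkit for longitudinal urinalysis monitoring in
substance-use treatment programs.

Mandatory treatment programs for stimulant and cannabis use disorders
monitor patients with scheduled urine tests — typically biweekly in an
initial high-demand phase, then monthly after the patient stabilizes (four
negative samples), with a positive test returning the patient to biweekly
testing. `uaprogress` is for clinicians and biostatisticians working with
such programs: it turns the raw long-format test log into patient-level
progress curves and a group-level weekly adherence series, and forecasts
that series with segment-wise ARIMA models.

## The model

Each test occasion scores

* **+1** for a negative urinalysis,
* **−1** for a positive urinalysis,
* **0** for a missed test.

A patient's *progress bar* is the cumulative score over their occasions.
At the group level, for program week *i*,

```
score_i          = sum of all per-test scores in week i
adjusted score_i = score_i / n_i,    n_i = number of urinalyses taken in week i
```

so the adjusted score lies in [−1, 1]; missed tests count in neither
numerator nor denominator. The adjusted series for a 52-week program is
split at week 27 (the approximate transition into the low-demand phase)
and each segment gets an ARIMA(p,d,q) analysis: augmented Dickey-Fuller
stationarity test, AIC order selection (or fixed orders), maximum-
likelihood fit, Box-Pierce residual diagnostics, and forecasts with
prediction intervals.

Because programs rarely publish patient-level test logs, the package also
ships a protocol-faithful simulator (two-phase state machine with
stabilization, relapse resets, missed-appointment schedule drift, and
dropout) so the entire pipeline is testable and demonstrable without real
data. See the methods vignette (`vignettes/progress-bar-methods.Rmd`) for
the full model account.

## Worked example

```r
library(uaprogress)

protocol <- protocol_config()                          # 52-week, biweekly/monthly
cohort   <- simulate_cohort(protocol,
                            simulation_config(n_patients = 312, seed = 1))
cohort
#> Urinalysis records: 6747 occasions, 312 patients, program length 52 weeks

eng <- filter_engagement(cohort)                       # >= 4 attended visits
eng$report
#> Filter 'engagement (>= 4 attended visits)': 312 patients in, 11 excluded, 301 retained

weekly <- group_weekly_scores(eng$records)
head(weekly[weekly$n > 0, ], 5)
#>   week score   n adjusted_score
#> 2    2    41 257      0.1595331
#> 3    3    10  36      0.2777778
#> 4    4    49 225      0.2177778
#> 5    5    10  68      0.1470588
#> 6    6    24 194      0.1237113

analysis <- run_two_phase_analysis(weekly)
analysis
#> Two-segment ARIMA analysis of the adjusted weekly score
#>   series: 52 weeks, split at week 27; 1 empty week(s) filled by 'zero'
#>   high_demand: ARIMA(1,1,2), ADF p 0.0782, Box-Pierce p 0.52, aic -28.34
#>   low_demand: ARIMA(0,1,1), ADF p 0.326, Box-Pierce p 0.791, aic -45.725

head(analysis$segments$high_demand$forecast, 3)
#>   step     point     lower     upper
#> 1    1 0.4398953 0.2252631 0.6545275
#> 2    2 0.4095783 0.1893580 0.6297987
#> 3    3 0.3933860 0.1733355 0.6134364
```

Reading the output: in week 2, 257 of the simulated patients took a test
and the net score was +41, an adjusted score of 0.16 (slightly more
negative than positive tests). Week 1 is empty — under a strict biweekly
schedule everyone tests on even weeks, and odd-week testing only grows
later as missed appointments shift schedules; the analysis fills such
weeks with 0 by default. The high-demand segment's forecasts continue the
adjusted score around 0.4 with a 95% interval of roughly ±0.22. The large
Box-Pierce p-values say the residuals of both segment models show no
detectable autocorrelation.

## Command-line interface

A thin Rscript front end wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "uaprogress.R", package = "uaprogress"))')
Rscript $CLI simulate  --out records.csv --seed 42
Rscript $CLI score     --records records.csv --out weekly.csv --curves curves.csv
Rscript $CLI filter    --records records.csv --rule engagement --out kept.csv --report report.json
Rscript $CLI summarize --records records.csv --attributes attrs.csv --out table1.csv
Rscript $CLI analyze   --weekly weekly.csv --out report.json --split-week 27 --auto
Rscript $CLI run       --config run.yaml --out-dir out/
```

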