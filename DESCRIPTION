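Package: uaprogress
Title: Urinalysis Progress-Bar Scoring and Time-Series Forecasting for
    Substance-Use Treatment Programs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scoring and forecasting toolkit for longitudinal urinalysis
    monitoring in mandatory substance-use treatment programs. Implements a
    trinary per-test score (+1 negative, -1 positive, 0 missed), cumulative
    per-patient progress-bar curves, a group-level weekly score standardized
    by weekly attendance, study-flow eligibility filters with descriptive
    cohort summaries, a protocol-faithful synthetic-cohort simulator
    (biweekly high-demand testing, stabilization after four negative
    samples, monthly low-demand testing, relapse-triggered reset, missed-
    appointment schedule drift, dropout), and a two-segment ARIMA analysis
    of the adjusted weekly score with augmented Dickey-Fuller stationarity
    testing, AIC order selection, Box-Pierce residual diagnostics, and
    forecasting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
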