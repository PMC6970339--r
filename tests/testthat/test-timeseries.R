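test_that("differencing follows the first-difference operator", {
  expect_equal(difference(c(1, 2, 4, 7), 1), c(1, 2, 3))
  expect_equal(difference(c(1, 2, 4, 7), 2), c(1, 1))
  x <- rnorm(10)
  expect_identical(difference(x, 0), x)
  expect_error(difference(1:3, 3), "too short")
})

test_that("undifference inverts difference exactly", {
  set.seed(501)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    d <- sample(0:3, 1)
    x <- rnorm(n)
    dx <- difference(x, d)
    expect_equal(undifference(dx, x[seq_len(d)]), x, tolerance = 1e-12)
  }
})

test_that("ADF test rejects white noise and retains random walks", {
  set.seed(502)
  rej_wn <- mean(replicate(60, adf_test(rnorm(300))$reject_unit_root))
  rej_rw <- mean(replicate(60, adf_test(cumsum(rnorm(300)))$reject_unit_root))
  expect_gte(rej_wn, 0.9)
  expect_lte(rej_rw, 0.1)
})

test_that("ADF test validates its input", {
  expect_error(adf_test(rnorm(8)), "too short")
  expect_error(adf_test(rep(1, 50)), "constant series")
  r <- adf_test(rnorm(100))
  expect_equal(r$lags_used, floor(99^(1 / 3)))
  expect_true(r$p_value >= 0 && r$p_value <= 1)
})

test_that("ARIMA fits recover known parameters", {
  set.seed(503)
  x <- arima.sim(list(ar = 0.6), n = 500)
  fit <- fit_arima(x, c(1, 0, 0))
  expect_lt(abs(fit$ar - 0.6), 0.1)
  expect_equal(length(fit$residuals), 500L)

  wn <- rnorm(400, mean = 3)
  fit0 <- fit_arima(wn, c(0, 0, 0), include_mean = TRUE)
  expect_lt(abs(fit0$intercept - mean(wn)), 3 / sqrt(400))
  expect_error(fit_arima(rnorm(5), c(3, 4, 7)), "too short")
  expect_warning(fit_arima(rnorm(20), c(3, 1, 3)), "small sample")
})

test_that("repeated fits on identical input are identical", {
  set.seed(504)
  x <- arima.sim(list(ar = 0.4, ma = 0.3), n = 120)
  f1 <- fit_arima(x, c(1, 0, 1))
  f2 <- fit_arima(x, c(1, 0, 1))
  expect_identical(f1$ar, f2$ar)
  expect_identical(f1$ma, f2$ma)
  expect_identical(f1$aic, f2$aic)
})

test_that("order selection finds the generating order for an AR(2)", {
  set.seed(505)
  hits_ar <- 0L
  hits_wn <- 0L
  reps <- 12L
  for (i in seq_len(reps)) {
    x <- arima.sim(list(ar = c(0.6, -0.3)), n = 500)
    o <- select_order(x, max_p = 3, max_d = 1, max_q = 2)
    if (o[1] == 2 && o[2] == 0) hits_ar <- hits_ar + 1L
    o2 <- select_order(rnorm(300), max_p = 2, max_d = 1, max_q = 2)
    if (o2[2] == 0 && sum(o2[c(1, 3)]) <= 1) hits_wn <- hits_wn + 1L
  }
  expect_gt(hits_ar, reps / 2)
  expect_gt(hits_wn, reps / 2)
})

test_that("Box-Pierce matches its definition and degenerate limit", {
  # a period-4 sequence whose lag-1 sample autocorrelation is exactly zero
  x <- rep(c(1, 0, -1, 0), 10)
  r <- box_pierce(x, n_lags = 1)
  expect_equal(r$q_statistic, 0, tolerance = 1e-12)
  expect_equal(r$p_value, 1, tolerance = 1e-12)

  set.seed(506)
  for (i in 1:50) {
    y <- rnorm(sample(50:200, 1))
    k <- sample(3:10, 1)
    r <- box_pierce(y, n_lags = k, n_fitted_params = 1)
    expect_equal(r$q_statistic, brute_box_pierce_q(y, k), tolerance = 1e-10)
    expect_gte(r$q_statistic, 0)
    expect_equal(r$df, k - 1)
    expect_true(r$p_value >= 0 && r$p_value <= 1)
  }
  expect_error(box_pierce(rnorm(50), n_lags = 2, n_fitted_params = 2),
               "exceed")
  expect_error(box_pierce(rnorm(5), n_lags = 10), "more residuals")
})

test_that("Ljung-Box variant matches the base implementation", {
  set.seed(507)
  y <- rnorm(100)
  r <- box_pierce(y, n_lags = 8, n_fitted_params = 2, type = "ljung-box")
  ref <- stats::Box.test(y, lag = 8, fitdf = 2, type = "Ljung-Box")
  expect_equal(r$q_statistic, unname(ref$statistic))
  expect_equal(r$p_value, ref$p.value)
})

test_that("phase split cuts at the configured week and conserves the series", {
  x <- rnorm(52)
  h <- split_phases(x, 27)
  expect_length(h$first, 26)
  expect_length(h$second, 26)
  expect_identical(c(h$first, h$second), x)
  h2 <- split_phases(x, 2)
  expect_length(h2$first, 1)
  expect_length(h2$second, 51)
  expect_error(split_phases(x, 1), "split_week")
  expect_error(split_phases(x, 53), "split_week")
})

test_that("forecasts obey closed-form limits and interval growth", {
  set.seed(508)
  wn <- rnorm(200, mean = 1.5)
  f0 <- fit_arima(wn, c(0, 0, 0), include_mean = TRUE)
  fc0 <- forecast_arima(f0, horizon = 5)
  expect_equal(fc0$point, rep(f0$intercept, 5), tolerance = 1e-8)

  rw <- cumsum(rnorm(200))
  f1 <- fit_arima(rw, c(0, 1, 0))
  fc1 <- forecast_arima(f1, horizon = 6)
  expect_equal(fc1$point, rep(rw[length(rw)], 6), tolerance = 1e-8)
  width <- fc1$upper - fc1$lower
  expect_gte(width[6], width[1])
  expect_true(all(fc1$lower <= fc1$point & fc1$point <= fc1$upper))
})

test_that("two-segment analysis reports every stage per segment", {
  set.seed(509)
  rec <- simulate_cohort(protocol_config(), simulation_config(
    n_patients = 150, p_positive_high = 0.1, seed = 61))
  w <- group_weekly_scores(rec)
  an <- suppressWarnings(
    run_two_phase_analysis(w, orders = list(c(3, 4, 7), c(2, 2, 3))))
  expect_named(an$segments, c("high_demand", "low_demand"))
  expect_equal(an$segments$high_demand$order, c(3L, 4L, 7L))
  expect_equal(an$segments$low_demand$order, c(2L, 2L, 3L))
  for (seg in an$segments) {
    expect_true(is.finite(seg$box_pierce$p_value))
    expect_true(is.finite(seg$adf$p_value))
    expect_equal(nrow(seg$forecast), 8L)
  }
  rep <- analysis_report(an)
  expect_equal(rep$segments$high_demand$order$q, 7L)
  expect_error(run_two_phase_analysis(rep(0, 52)), "degenerate")
})

test_that("a high-abstinence cohort forecasts a rising first-segment trend", {
  rec <- simulate_cohort(protocol_config(), simulation_config(
    n_patients = 300, p_positive_high = 0.1, p_positive_low = 0.05,
    seed = 62))
  w <- group_weekly_scores(rec)
  an <- run_two_phase_analysis(w, fill = "interpolate")
  fc <- an$segments$high_demand$forecast
  slope <- stats::coef(stats::lm(point ~ step, data = fc))[["step"]]
  expect_gte(slope, 0)
})
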