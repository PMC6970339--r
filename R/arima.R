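#' Difference a series
#'
#' Applies the first-difference operator `d` times; `d = 0` returns the
#' series unchanged. The output is `d` elements shorter than the input.
#'
#' @param x Numeric series.
#' @param d Non-negative integer differencing order.
#' @return Numeric vector of length `length(x) - d`.
#' @seealso [undifference()] for the exact inverse.
#' @export
difference <- function(x, d) {
  stopifnot(d >= 0, d == floor(d))
  if (length(x) <= d)
    stop("series of length ", length(x), " too short to difference ",
         d, " times", call. = FALSE)
  if (d == 0L) return(as.numeric(x))
  diff(as.numeric(x), differences = d)
}

#' Invert differencing
#'
#' Reconstructs the original series from a `d`-times differenced series
#' and the `d` leading values that differencing discarded; exact inverse
#' of [difference()].
#'
#' @param dx Differenced series.
#' @param init The first `d` values of the original series, oldest first.
#' @return Numeric vector of length `length(dx) + length(init)`.
#' @export
undifference <- function(dx, init) {
  d <- length(init)
  out <- as.numeric(dx)
  for (j in rev(seq_len(d))) {
    # prepend the j-th order head value, then cumulate one level up
    head_j <- difference(init, j - 1L)[1L]
    out <- cumsum(c(head_j, out))
  }
  out
}

#' Fit an ARIMA(p, d, q) model
#'
#' Maximum-likelihood fit via [stats::arima()] (method `"ML"`, fixed
#' optimizer settings so repeated fits on identical input are
#' reproducible). A mean (intercept) is included for `d = 0` models, as
#' differencing absorbs the level otherwise. A warning is emitted when the
#' differenced sample is small relative to the parameter count
#' (`length - d < 3 * (p + q + 1)`).
#'
#' @param x Numeric series.
#' @param order Integer vector `c(p, d, q)`; the degenerate order
#'   `(0, 0, 0)` is accepted only with `include_mean = TRUE`.
#' @param include_mean Include a mean term (default: `d == 0`).
#' @return List of class `ua_arima`: `order`, `ar`, `ma`, `intercept`,
#'   `residuals` (length `length(x) - d`), `sigma2`, `aic`, `loglik`,
#'   `n`, and the underlying `stats::arima` fit in `model`.
#' @export
fit_arima <- function(x, order, include_mean = order[2L] == 0L) {
  x <- as.numeric(x)
  order <- as.integer(order)
  if (length(order) != 3L || anyNA(order) || any(order < 0))
    stop("order must be three non-negative integers (p, d, q)",
         call. = FALSE)
  p <- order[1L]; d <- order[2L]; q <- order[3L]
  if (p + q == 0L && d == 0L && !include_mean)
    stop("degenerate model: p + q = 0, d = 0 and no mean", call. = FALSE)
  if (length(x) - d <= p + q + 1L)
    stop("series too short for order (", p, ",", d, ",", q, "): need ",
         "length - d > p + q + 1", call. = FALSE)
  if (length(x) - d < 3L * (p + q + 1L))
    warning("small sample for order (", p, ",", d, ",", q, "): ",
            length(x) - d, " differenced points for ", p + q,
            " lag coefficients", call. = FALSE)
  fit <- tryCatch(
    stats::arima(x, order = order, include.mean = include_mean,
                 method = "ML", optim.control = list(maxit = 500L)),
    error = function(e) stop("ARIMA(", p, ",", d, ",", q,
                             ") fit failed: ", conditionMessage(e),
                             call. = FALSE))
  cf <- stats::coef(fit)
  res <- as.numeric(stats::residuals(fit))
  if (d > 0L) res <- res[-seq_len(d)]
  structure(list(order = order,
                 ar = unname(cf[grep("^ar", names(cf))]),
                 ma = unname(cf[grep("^ma", names(cf))]),
                 intercept = if ("intercept" %in% names(cf))
                   unname(cf["intercept"]) else NA_real_,
                 residuals = res, sigma2 = fit$sigma2,
                 aic = fit$aic, loglik = fit$loglik,
                 n = length(x), model = fit),
            class = "ua_arima")
}

#' @export
print.ua_arima <- function(x, ...) {
  cat("ARIMA(", paste(x$order, collapse = ","), ") fit on ", x$n,
      " points: aic = ", format(x$aic, digits = 5L),
      ", loglik = ", format(x$loglik, digits = 5L), "\n", sep = "")
  if (length(x$ar)) cat("  ar: ", paste(format(x$ar, digits = 3L),
                                        collapse = " "), "\n", sep = "")
  if (length(x$ma)) cat("  ma: ", paste(format(x$ma, digits = 3L),
                                        collapse = " "), "\n", sep = "")
  if (!is.na(x$intercept))
    cat("  mean: ", format(x$intercept, digits = 4L), "\n", sep = "")
  invisible(x)
}

#' Select an ARIMA order by stationarity testing and AIC
#'
#' Chooses `d` as the smallest differencing order in `0..max_d` whose
#' differenced series rejects a unit root under [adf_test()] at `alpha`,
#' then searches the full `(p, q)` grid for the AIC-minimizing model at
#' that `d`. Ties are broken toward fewer total lag coefficients
#' (`p + q`), then toward smaller `p`. Candidate fits that fail to
#' converge are skipped.
#'
#' @param x Numeric series.
#' @param max_p,max_d,max_q Grid bounds (defaults 3, 2, 3).
#' @param alpha Significance level for the stationarity decision.
#' @return Integer vector `c(p, d, q)`.
#' @export
select_order <- function(x, max_p = 3L, max_d = 2L, max_q = 3L,
                         alpha = 0.05) {
  stopifnot(max_p >= 0, max_d >= 0, max_q >= 0)
  x <- as.numeric(x)
  d_sel <- NA_integer_
  for (d in 0:max_d) {
    ok <- tryCatch(adf_test(difference(x, d), alpha = alpha)$reject_unit_root,
                   error = function(e) FALSE)
    if (ok) { d_sel <- d; break }
  }
  if (is.na(d_sel))
    stop("no differencing order in 0..", max_d,
         " yields a stationary series under the ADF test", call. = FALSE)
  best <- NULL
  for (p in 0:max_p) for (q in 0:max_q) {
    if (p + q == 0L && d_sel == 0L) {
      # mean-only model is a valid candidate
      fit <- tryCatch(fit_arima(x, c(0L, 0L, 0L), include_mean = TRUE),
                      error = function(e) NULL)
    } else {
      fit <- tryCatch(suppressWarnings(fit_arima(x, c(p, d_sel, q))),
                      error = function(e) NULL)
    }
    if (is.null(fit)) next
    cand <- list(order = c(p, d_sel, q), aic = fit$aic)
    if (is.null(best) || cand$aic < best$aic - 1e-9 ||
        (abs(cand$aic - best$aic) <= 1e-9 &&
         (p + q < sum(best$order[c(1L, 3L)]) ||
          (p + q == sum(best$order[c(1L, 3L)]) && p < best$order[1L]))))
      best <- cand
  }
  if (is.null(best))
    stop("no candidate ARIMA model converged on the grid", call. = FALSE)
  as.integer(best$order)
}

#' Box-Pierce portmanteau test for residual autocorrelation
#'
#' Computes `Q = T * sum_{k=1..n_lags} rho_k^2`, where `rho_k` is the
#' lag-`k` sample autocorrelation of the residuals, and refers it to a
#' chi-square distribution with `n_lags - n_fitted_params` degrees of
#' freedom. A large p-value (no detectable residual autocorrelation)
#' supports using the fitted model for prediction. The Ljung-Box variant,
#' which corrects the statistic's small-sample distribution, is available
#' via `type`.
#'
#' @param residuals Residual series.
#' @param n_lags Number of autocorrelation lags to pool; must exceed
#'   `n_fitted_params`.
#' @param n_fitted_params Number of estimated ARMA coefficients (`p + q`),
#'   subtracted from the degrees of freedom.
#' @param type `"box-pierce"` (default) or `"ljung-box"`.
#' @return List of class `ua_portmanteau`: `q_statistic`, `df`, `p_value`,
#'   `n_lags`, `n_fitted_params`, `type`.
#' @export
box_pierce <- function(residuals, n_lags, n_fitted_params = 0L,
                       type = c("box-pierce", "ljung-box")) {
  type <- match.arg(type)
  residuals <- as.numeric(residuals)
  if (n_lags <= n_fitted_params)
    stop("n_lags must exceed n_fitted_params", call. = FALSE)
  if (length(residuals) <= n_lags)
    stop("need more residuals than lags", call. = FALSE)
  bt <- stats::Box.test(residuals, lag = n_lags, fitdf = n_fitted_params,
                        type = if (type == "box-pierce") "Box-Pierce"
                        else "Ljung-Box")
  structure(list(q_statistic = unname(bt$statistic),
                 df = unname(bt$parameter), p_value = bt$p.value,
                 n_lags = as.integer(n_lags),
                 n_fitted_params = as.integer(n_fitted_params),
                 type = type),
            class = "ua_portmanteau")
}

#' @export
print.ua_portmanteau <- function(x, ...) {
  cat(if (x$type == "box-pierce") "Box-Pierce" else "Ljung-Box",
      " test: Q = ", format(x$q_statistic, digits = 4L), ", df = ", x$df,
      ", p-value = ", format(x$p_value, digits = 3L), "\n", sep = "")
  invisible(x)
}

#' Split a weekly series into the two treatment phases
#'
#' Cuts the series at `split_week`: the first segment covers weeks
#' `1..split_week - 1` (the high-demand half; 26 points for a 52-week
#' program split at week 27) and the second covers `split_week..end` (the
#' low-demand half). Concatenating the halves reproduces the input.
#'
#' @param x Numeric series indexed by week, week 1 first.
#' @param split_week First week of the second segment (default 27).
#' @return List with elements `first` and `second`.
#' @export
split_phases <- function(x, split_week = 27L) {
  if (split_week <= 1L || split_week > length(x))
    stop("split_week must lie in (1, length(x)]", call. = FALSE)
  list(first = x[seq_len(split_week - 1L)],
       second = x[split_week:length(x)])
}

#' Forecast from a fitted ARIMA model
#'
#' Point forecasts and normal-theory prediction intervals `horizon` steps
#' ahead. For integrated models the interval width grows with the horizon
#' as forecast-error variance accumulates.
#'
#' @param fit A `ua_arima` object from [fit_arima()].
#' @param horizon Number of steps ahead (>= 1).
#' @param level Interval coverage (default 0.95).
#' @return Data frame of class `ua_forecast` with columns `step`, `point`,
#'   `lower`, `upper` and attribute `level`.
#' @export
forecast_arima <- function(fit, horizon, level = 0.95) {
  stopifnot(inherits(fit, "ua_arima"), horizon >= 1, level > 0, level < 1)
  pr <- stats::predict(fit$model, n.ahead = horizon)
  z <- stats::qnorm((1 + level) / 2)
  structure(data.frame(step = seq_len(horizon),
                       point = as.numeric(pr$pred),
                       lower = as.numeric(pr$pred) - z * as.numeric(pr$se),
                       upper = as.numeric(pr$pred) + z * as.numeric(pr$se)),
            level = level, class = c("ua_forecast", "data.frame"))
}

#' Two-segment ARIMA analysis of the adjusted weekly score
#'
#' The full statistical stage: completes the adjusted-score series (weeks
#' with no tests filled per `fill`), splits it into the high- and
#' low-demand segments at `split_week`, and for each segment runs the ADF
#' stationarity test, fixes or selects the ARIMA order, fits the model,
#' checks the residuals with the Box-Pierce test (`n_lags` defaults to
#' `min(10, floor(T/5))`, raised to `p + q + 1` when the order demands
#' it), and forecasts `horizon` weeks ahead.
#'
#' @param weekly A `ua_weekly` data frame from [group_weekly_scores()] (or
#'   a numeric series with `NA` for missing weeks).
#' @param split_week First week of the second segment (default 27).
#' @param fill Missing-week policy for [fill_missing_adjusted()].
#' @param orders `NULL` to select orders by [select_order()], or a list of
#'   two `c(p, d, q)` vectors for the first and second segments.
#' @param max_p,max_d,max_q Grid bounds when `orders` is `NULL`.
#' @param alpha Significance level used by the ADF decision.
#' @param horizon Forecast horizon in weeks (default 8).
#' @param level Forecast interval coverage (default 0.95).
#' @return List of class `ua_analysis`: the completed `series`, the
#'   indices of `filled_weeks`, `split_week`, `fill` policy, and a
#'   `segments` list whose `high_demand` and `low_demand` elements each
#'   carry `series`, `adf`, `order`, `fit`, `box_pierce` and `forecast`.
#' @export
run_two_phase_analysis <- function(weekly, split_week = 27L,
                                   fill = c("zero", "interpolate"),
                                   orders = NULL, max_p = 3L, max_d = 2L,
                                   max_q = 3L, alpha = 0.05, horizon = 8L,
                                   level = 0.95) {
  fill <- match.arg(fill)
  raw <- if (is.data.frame(weekly)) weekly$adjusted_score else
    as.numeric(weekly)
  filled_weeks <- which(is.na(raw))
  series <- fill_missing_adjusted(raw, fill)
  if (stats::sd(series) == 0)
    stop("degenerate series: adjusted score is constant, nothing to model",
         call. = FALSE)
  if (!is.null(orders) && length(orders) != 2L)
    stop("orders must be NULL or a list of two (p,d,q) vectors",
         call. = FALSE)
  halves <- split_phases(series, split_week)
  labels <- c("high_demand", "low_demand")
  segments <- vector("list", 2L)
  names(segments) <- labels
  for (k in 1:2) {
    seg <- halves[[k]]
    with_stage <- function(stage, expr) {
      tryCatch(expr, error = function(e)
        stop(labels[k], " segment, ", stage, " stage: ",
             conditionMessage(e), call. = FALSE))
    }
    adf <- with_stage("stationarity", adf_test(seg, alpha = alpha))
    order <- if (is.null(orders))
      with_stage("order selection",
                 select_order(seg, max_p = max_p, max_d = max_d,
                              max_q = max_q, alpha = alpha))
    else as.integer(orders[[k]])
    fit <- with_stage("model fit",
                      if (sum(order) == 0L)
                        fit_arima(seg, order, include_mean = TRUE)
                      else fit_arima(seg, order))
    n_par <- order[1L] + order[3L]
    n_lags <- max(min(10L, floor(length(seg) / 5)), n_par + 1L)
    bp <- with_stage("portmanteau",
                     box_pierce(fit$residuals, n_lags = n_lags,
                                n_fitted_params = n_par))
    fc <- with_stage("forecast", forecast_arima(fit, horizon, level))
    segments[[k]] <- list(series = seg, adf = adf, order = order,
                          fit = fit, box_pierce = bp, forecast = fc)
  }
  structure(list(series = series, filled_weeks = filled_weeks,
                 split_week = as.integer(split_week), fill = fill,
                 alpha = alpha, segments = segments),
            class = "ua_analysis")
}

#' @export
print.ua_analysis <- function(x, ...) {
  cat("Two-segment ARIMA analysis of the adjusted weekly score\n")
  cat("  series: ", length(x$series), " weeks, split at week ",
      x$split_week, "; ", length(x$filled_weeks),
      " empty week(s) filled by '", x$fill, "'\n", sep = "")
  for (nm in names(x$segments)) {
    s <- x$segments[[nm]]
    cat("  ", nm, ": ARIMA(", paste(s$order, collapse = ","),
        "), ADF p ", format(s$adf$p_value, digits = 3L),
        ", Box-Pierce p ", format(s$box_pierce$p_value, digits = 3L),
        ", aic ", format(s$fit$aic, digits = 5L), "\n", sep = "")
  }
  invisible(x)
}
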