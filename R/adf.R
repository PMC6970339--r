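# Critical values of the Dickey-Fuller tau statistic for the regression
# with constant and linear trend, from the published tables (Fuller 1976,
# Table 8.5.2; Banerjee, Dolado, Galbraith & Hendry 1993, Table 4.2).
# Rows: sample sizes 25, 50, 100, 250, 500, Inf. Columns: lower-tail
# probabilities 0.01, 0.025, 0.05, 0.10, 0.90, 0.95, 0.975, 0.99.
df_tau_probs <- c(0.01, 0.025, 0.05, 0.10, 0.90, 0.95, 0.975, 0.99)
df_tau_sizes <- c(25, 50, 100, 250, 500, 1e5)
df_tau_table <- -rbind(
  c(4.38, 3.95, 3.60, 3.24, 1.14, 0.80, 0.50, 0.15),
  c(4.15, 3.80, 3.50, 3.18, 1.19, 0.87, 0.58, 0.24),
  c(4.04, 3.73, 3.45, 3.15, 1.22, 0.90, 0.62, 0.28),
  c(3.99, 3.69, 3.43, 3.13, 1.23, 0.92, 0.64, 0.31),
  c(3.98, 3.68, 3.42, 3.13, 1.24, 0.93, 0.65, 0.32),
  c(3.96, 3.66, 3.41, 3.12, 1.25, 0.94, 0.66, 0.33))

#' Augmented Dickey-Fuller unit-root test
#'
#' Tests the null hypothesis that a series has a unit root (is
#' non-stationary) against the alternative of (trend-)stationarity, using
#' the regression of the first difference on a constant, a linear trend,
#' the lagged level and `lags` lagged differences. The tau statistic is
#' the t-ratio of the lagged-level coefficient; its p-value is obtained by
#' interpolation in the published Dickey-Fuller table for the
#' constant-plus-trend case. Rejection (small p) indicates stationarity.
#'
#' @param x Numeric series.
#' @param lags Number of augmentation lags; default
#'   `floor((length(x) - 1)^(1/3))`.
#' @param alpha Significance level for the stationarity decision
#'   (default 0.05).
#' @return List of class `ua_adf` with `statistic`, `p_value` (clamped to
#'   the table range `[0.01, 0.99]`), `lags_used`, `alpha` and
#'   `reject_unit_root`.
#' @export
adf_test <- function(x, lags = NULL, alpha = 0.05) {
  x <- as.numeric(x)
  if (anyNA(x)) stop("series contains NA", call. = FALSE)
  if (is.null(lags)) lags <- floor((length(x) - 1)^(1 / 3))
  lags <- as.integer(lags)
  if (lags < 0) stop("lags must be >= 0", call. = FALSE)
  if (length(x) < lags + 10L)
    stop("series too short for ", lags, " lags (need >= ", lags + 10L,
         " observations)", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("constant series: unit-root regression is degenerate",
         call. = FALSE)

  dx <- diff(x)
  n <- length(dx) - lags
  yd <- dx[(lags + 1L):length(dx)]
  ylag <- x[(lags + 1L):(length(x) - 1L)]
  tt <- seq_len(n)
  if (lags > 0L) {
    dlag <- sapply(seq_len(lags), function(j) dx[(lags + 1L - j):(length(dx) - j)])
    fit <- stats::lm(yd ~ ylag + tt + dlag)
  } else {
    fit <- stats::lm(yd ~ ylag + tt)
  }
  ct <- stats::coef(summary(fit))
  stat <- ct["ylag", "t value"]

  # interpolate critical values to this sample size, then the statistic
  # to a probability; outside the table the p-value is clamped
  cv <- apply(df_tau_table, 2L, function(col)
    stats::approx(df_tau_sizes, col, xout = n, rule = 2)$y)
  p <- stats::approx(cv, df_tau_probs, xout = stat, rule = 2)$y
  structure(list(statistic = unname(stat), p_value = p,
                 lags_used = lags, alpha = alpha,
                 reject_unit_root = p < alpha),
            class = "ua_adf")
}

#' @export
print.ua_adf <- function(x, ...) {
  cat("Augmented Dickey-Fuller test (constant + trend)\n",
      "tau = ", format(x$statistic, digits = 4L),
      ", lags = ", x$lags_used,
      ", p-value ", if (x$p_value <= 0.01) "<= 0.01"
      else if (x$p_value >= 0.99) ">= 0.99"
      else paste0("= ", format(x$p_value, digits = 3L)), "\n",
      if (x$reject_unit_root)
        "unit root rejected: series treated as stationary\n"
      else "unit root not rejected\n", sep = "")
  invisible(x)
}
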