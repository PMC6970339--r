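#' Score a urinalysis result
#'
#' The per-test score at the heart of the progress bar: a negative test
#' scores +1, a positive test scores -1, and a missed test scores 0.
#'
#' @param result Character vector of results (see [ua_results]).
#' @return Integer vector of scores, same length as `result`.
#' @export
score_result <- function(result) {
  bad <- !(result %in% ua_results)
  if (any(bad))
    stop("invalid result token(s): ",
         paste0("'", unique(result[bad]), "'", collapse = ", "),
         call. = FALSE)
  unname(c(negative = 1L, positive = -1L, missed = 0L)[result])
}

#' Per-patient cumulative progress-bar series
#'
#' For each patient, the running sum of per-test scores over their test
#' occasions in week order. A steadily increasing curve reflects sustained
#' abstinence; a drop marks a relapse. Consecutive values differ by exactly
#' -1, 0 or +1 by construction.
#'
#' @param records A `ua_records` object.
#' @return Data frame with columns `patient_id`, `week`,
#'   `cumulative_score`, class `ua_progress`, ordered by patient then week.
#' @export
patient_progress_series <- function(records) {
  records <- if (inherits(records, "ua_records")) records else
    as_ua_records(records)
  out <- as.data.frame(records)[c("patient_id", "week")]
  sc <- score_result(records$result)
  out$cumulative_score <- if (nrow(out))
    as.integer(unlist(lapply(split(sc, factor(out$patient_id,
                                              unique(out$patient_id))),
                             cumsum), use.names = FALSE))
  else integer()
  structure(out, class = c("ua_progress", "data.frame"))
}

#' Group-level weekly scores and adjusted scores
#'
#' Aggregates all patients onto the program-week axis. For each week `i` in
#' `1..program_length`: `score` is the sum of per-test scores over every
#' occasion recorded in that week; `n` is the number of urinalyses actually
#' taken that week (missed occasions are excluded from `n` -- a missed test
#' contributes 0 to the numerator and nothing to the denominator); and
#' `adjusted_score = score / n`, the attendance-standardized group score in
#' `[-1, 1]`, `NA` for weeks in which no one tested.
#'
#' @param records A `ua_records` object.
#' @param program_length Program length in weeks; defaults to the record
#'   set's own attribute.
#' @return Data frame with one row per week and columns `week`, `score`,
#'   `n`, `adjusted_score`, class `ua_weekly`.
#' @export
group_weekly_scores <- function(records,
                                program_length = uaprogress::program_length(records)) {
  records <- if (inherits(records, "ua_records")) records else
    as_ua_records(records, program_length)
  weeks <- seq_len(program_length)
  sc <- score_result(records$result)
  wk <- factor(records$week, levels = weeks)
  score <- as.integer(tapply(sc, wk, sum, default = 0L))
  n <- as.integer(tapply(records$result != "missed", wk, sum, default = 0L))
  adjusted <- ifelse(n > 0L, score / n, NA_real_)
  structure(data.frame(week = weeks, score = score, n = n,
                       adjusted_score = adjusted),
            class = c("ua_weekly", "data.frame"))
}

#' Fill missing weekly adjusted scores
#'
#' The time-series stage needs a complete series; weeks in which no patient
#' tested have an undefined adjusted score. `"zero"` (the default) fills
#' them with 0 -- the conservative choice, fabricating no signal; an
#' all-negative testing week would score +1 and an all-positive week -1, so
#' 0 is the neutral midpoint. `"interpolate"` fills linearly between the
#' nearest observed neighbours, extending flat at the edges.
#'
#' @param weekly A `ua_weekly` data frame (from [group_weekly_scores()]) or
#'   a numeric vector with `NA` for missing weeks.
#' @param policy `"zero"` or `"interpolate"`.
#' @return Numeric vector, one value per week, no `NA`.
#' @export
fill_missing_adjusted <- function(weekly, policy = c("zero", "interpolate")) {
  policy <- match.arg(policy)
  x <- if (is.data.frame(weekly)) weekly$adjusted_score else as.numeric(weekly)
  miss <- is.na(x)
  if (!any(miss)) return(x)
  if (policy == "zero") {
    x[miss] <- 0
    return(x)
  }
  if (all(miss))
    stop("cannot interpolate: no observed adjusted scores", call. = FALSE)
  if (sum(!miss) == 1L) return(rep(x[!miss], length(x)))
  idx <- seq_along(x)
  stats::approx(idx[!miss], x[!miss], xout = idx, rule = 2)$y
}

#' @export
plot.ua_progress <- function(x, ...) {
  ids <- unique(x$patient_id)
  plot(NULL, xlim = range(x$week), ylim = range(x$cumulative_score),
       xlab = "program week", ylab = "cumulative score", ...)
  for (id in ids) {
    s <- x[x$patient_id == id, ]
    graphics::lines(s$week, s$cumulative_score,
                    col = grDevices::grey(0.2, 0.4))
  }
  invisible(x)
}

#' @export
plot.ua_weekly <- function(x, which = c("adjusted", "score"), ...) {
  which <- match.arg(which)
  y <- if (which == "adjusted") x$adjusted_score else x$score
  plot(x$week, y, type = "o", pch = 16, cex = 0.6, xlab = "program week",
       ylab = if (which == "adjusted") "adjusted score" else "score", ...)
  invisible(x)
}
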