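# Per-patient attendance summaries used by all filters. An "outpatient
# visit" is operationalized as an attended test occasion (result != missed):
# visits and urinalyses are coupled in this protocol.
patient_attendance <- function(records) {
  ids <- unique(records$patient_id)
  att <- records[records$result != "missed", , drop = FALSE]
  f <- factor(att$patient_id, levels = ids)
  data.frame(
    patient_id = ids,
    n_attended = as.integer(tapply(rep(1L, nrow(att)), f, sum, default = 0L)),
    last_attended = as.integer(tapply(att$week, f, max, default = NA)),
    stringsAsFactors = FALSE
  )
}

filter_report <- function(rule, n_input, n_retained) {
  structure(list(rule = rule, n_input = n_input,
                 n_excluded = n_input - n_retained, n_retained = n_retained),
            class = "ua_filter_report")
}

#' @export
print.ua_filter_report <- function(x, ...) {
  cat("Filter '", x$rule, "': ", x$n_input, " patients in, ",
      x$n_excluded, " excluded, ", x$n_retained, " retained\n", sep = "")
  invisible(x)
}

keep_patients <- function(records, keep_ids, rule) {
  ids <- unique(records$patient_id)
  out <- records[records$patient_id %in% keep_ids, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "program_length") <- program_length(records)
  class(out) <- c("ua_records", "data.frame")
  list(records = out,
       report = filter_report(rule, length(ids), length(keep_ids)))
}

#' Engagement filter: minimum attended visits
#'
#' Retains patients with at least `min_visits` attended test occasions
#' (result other than missed), ensuring an adequate observation period for
#' the time-series stage. Patients below the threshold failed treatment
#' engagement.
#'
#' @param records A `ua_records` object.
#' @param min_visits Minimum number of attended occasions (default 4).
#' @return List with elements `records` (retained record set) and `report`
#'   (a `ua_filter_report` with input/excluded/retained patient counts).
#' @export
filter_engagement <- function(records, min_visits = 4L) {
  stopifnot(min_visits >= 1)
  att <- patient_attendance(records)
  keep_patients(records, att$patient_id[att$n_attended >= min_visits],
                sprintf("engagement (>= %d attended visits)", min_visits))
}

#' Recency filter: maximum gap before the study end
#'
#' Excludes patients whose most recent attended visit was more than
#' `max_gap` weeks before the end of the study period; long absences are
#' likely confounded (e.g. re-arrest restarting treatment). A patient with
#' no attended visits has no most recent visit and is excluded by
#' convention.
#'
#' @param records A `ua_records` object.
#' @param study_end_week Final week of the study period.
#' @param max_gap Maximum tolerated gap in weeks (default 26).
#' @return List with `records` and `report`, as [filter_engagement()].
#' @export
filter_recency <- function(records, study_end_week, max_gap = 26L) {
  stopifnot(study_end_week >= 1)
  att <- patient_attendance(records)
  ok <- !is.na(att$last_attended) &
    att$last_attended >= study_end_week - max_gap
  keep_patients(records, att$patient_id[ok],
                sprintf("recency (last visit within %d weeks of week %d)",
                        max_gap, study_end_week))
}

#' Completion filter: consistent appearance across the program
#'
#' Retains patients who appeared consistently throughout the program,
#' operationalized as at least one attended occasion in each program half
#' (weeks `1..floor(program_length/2)` and the remainder) and a last
#' attended occasion within `max_gap` weeks of the program end.
#'
#' @param records A `ua_records` object.
#' @param program_length Program length in weeks.
#' @param max_gap Maximum gap between last attendance and program end
#'   (default 26).
#' @return List with `records` and `report`, as [filter_engagement()].
#' @export
filter_completers <- function(records,
                              program_length = uaprogress::program_length(records),
                              max_gap = 26L) {
  stopifnot(program_length >= 1)
  half <- floor(program_length / 2)
  att <- records[records$result != "missed", , drop = FALSE]
  ids <- unique(records$patient_id)
  f <- factor(att$patient_id, levels = ids)
  in_first <- as.logical(tapply(att$week <= half, f, any, default = FALSE))
  in_second <- as.logical(tapply(att$week > half, f, any, default = FALSE))
  last <- as.integer(tapply(att$week, f, max, default = NA))
  ok <- in_first & in_second & !is.na(last) & last >= program_length - max_gap
  keep_patients(records, ids[ok], "completion (attendance in both halves)")
}

# Round half away from zero to `digits` decimals (Table-1 convention;
# base round() rounds half to even).
round_half_away <- function(x, digits = 1L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Descriptive cohort summary
#'
#' Builds a Table-1 style summary from a patient attribute table: one row
#' per logical attribute with its count and one-decimal percentage of the
#' denominator (rounded half away from zero), and one row per numeric
#' attribute with its mean and standard deviation.
#'
#' @param attributes Data frame with a `patient_id` column plus logical
#'   (counted) and/or numeric (mean +/- sd) attribute columns.
#' @param denominator Denominator for percentages; defaults to the number
#'   of patients in `attributes`.
#' @return Data frame with columns `label`, `count`, `percent`, `mean`,
#'   `sd` (`NA` where not applicable), class `ua_cohort_summary`.
#' @export
summarize_cohort <- function(attributes, denominator = nrow(attributes)) {
  stopifnot(is.data.frame(attributes))
  if (denominator < 1) stop("denominator must be >= 1", call. = FALSE)
  cols <- setdiff(names(attributes), "patient_id")
  if (!length(cols))
    return(structure(data.frame(label = character(), count = integer(),
                                percent = double(), mean = double(),
                                sd = double()),
                     denominator = denominator,
                     class = c("ua_cohort_summary", "data.frame")))
  rows <- lapply(cols, function(nm) {
    v <- attributes[[nm]]
    if (is.logical(v)) {
      cnt <- sum(v, na.rm = TRUE)
      data.frame(label = nm, count = cnt,
                 percent = round_half_away(100 * cnt / denominator, 1L),
                 mean = NA_real_, sd = NA_real_)
    } else if (is.numeric(v)) {
      data.frame(label = nm, count = NA_integer_, percent = NA_real_,
                 mean = mean(v, na.rm = TRUE), sd = stats::sd(v, na.rm = TRUE))
    } else {
      stop("attribute column '", nm, "' is neither logical nor numeric",
           call. = FALSE)
    }
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  structure(out, denominator = denominator,
            class = c("ua_cohort_summary", "data.frame"))
}
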