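#' Default pipeline configuration
#'
#' A fully-populated configuration list for [run_pipeline()]: protocol and
#' simulation settings at their defaults, the engagement (4 visits) and
#' recency (26 weeks) filters enabled, and an auto-selected two-segment
#' analysis split at week 27 with zero fill.
#'
#' @param seed Master seed for the simulation.
#' @return A nested configuration list.
#' @export
default_run_config <- function(seed = 1L) {
  list(protocol = unclass(protocol_config()),
       simulation = unclass(simulation_config(seed = seed)),
       records = NULL,
       attributes = NULL,
       filters = list(engagement_min_visits = 4L, recency_max_gap = 26L),
       analysis = list(split_week = 27L, fill = "zero", orders = NULL,
                       max_p = 3L, max_d = 2L, max_q = 3L, alpha = 0.05,
                       horizon = 8L, level = 0.95))
}

validate_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  base <- default_run_config()
  for (nm in names(base))
    if (is.null(config[[nm]]) && !nm %in% c("records", "attributes"))
      config[[nm]] <- base[[nm]]
  for (nm in names(base$analysis))
    if (is.null(config$analysis[[nm]]) && nm != "orders")
      config$analysis[[nm]] <- base$analysis[[nm]]
  config$protocol <- do.call(protocol_config, config$protocol)
  if (!is.null(config$simulation))
    config$simulation <- do.call(simulation_config, config$simulation)
  if (is.null(config$simulation) && is.null(config$records))
    stop("config needs either a simulation block or a records path",
         call. = FALSE)
  config
}

log_stage <- function(...) message("[uaprogress] ", ...)

#' Run the full pipeline
#'
#' Executes the stages end to end -- simulate (or read) records, score,
#' filter, optionally summarize, analyze -- writing every artifact under
#' `out_dir`: `records.csv`, `progress_curves.csv`, `weekly_scores.csv`,
#' `filter_reports.json`, optionally `cohort_summary.csv`, and
#' `analysis_report.json`. Stage progress and row counts are logged to
#' stderr; all machine output goes to files. The run is fully
#' deterministic given the configured seed.
#'
#' @param config A configuration list (see [default_run_config()]) or the
#'   path to a YAML file with the same structure.
#' @param out_dir Output directory, created if absent.
#' @return Invisibly, a list with the artifact paths, the filter reports,
#'   and the `ua_analysis` object.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = ".") {
  config <- validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  if (!is.null(config$records)) {
    log_stage("reading records from ", config$records)
    records <- read_records(config$records,
                            program_length = config$protocol$program_length)
  } else {
    log_stage("simulating cohort: n = ", config$simulation$n_patients,
              ", seed = ", config$simulation$seed)
    records <- simulate_cohort(config$protocol, config$simulation)
  }
  n_raw <- nrow(records)
  paths$records <- file.path(out_dir, "records.csv")
  write_records(records, paths$records)
  log_stage("records: ", n_raw, " occasions, ",
            length(unique(records$patient_id)), " patients")

  reports <- list()
  f <- config$filters
  if (!is.null(f$engagement_min_visits)) {
    r <- filter_engagement(records, f$engagement_min_visits)
    records <- r$records
    reports$engagement <- unclass(r$report)
    log_stage("engagement filter: ", r$report$n_input, " -> ",
              r$report$n_retained, " patients")
  }
  if (!is.null(f$recency_max_gap)) {
    r <- filter_recency(records, config$protocol$program_length,
                        f$recency_max_gap)
    records <- r$records
    reports$recency <- unclass(r$report)
    log_stage("recency filter: ", r$report$n_input, " -> ",
              r$report$n_retained, " patients")
  }
  stopifnot(nrow(records) <= n_raw)
  paths$filter_reports <- file.path(out_dir, "filter_reports.json")
  jsonlite::write_json(reports, paths$filter_reports, auto_unbox = TRUE,
                       pretty = TRUE)

  progress <- patient_progress_series(records)
  paths$progress <- file.path(out_dir, "progress_curves.csv")
  utils::write.csv(progress, paths$progress, row.names = FALSE)
  log_stage("progress curves: ", nrow(progress), " rows")
  stopifnot(nrow(progress) == nrow(records))

  weekly <- group_weekly_scores(records, config$protocol$program_length)
  paths$weekly <- file.path(out_dir, "weekly_scores.csv")
  utils::write.csv(weekly, paths$weekly, row.names = FALSE)
  log_stage("weekly scores: ", nrow(weekly), " weeks, ",
            sum(is.na(weekly$adjusted_score)), " empty")

  summary_tbl <- NULL
  if (!is.null(config$attributes)) {
    attrs <- utils::read.csv(config$attributes, stringsAsFactors = FALSE)
    for (nm in setdiff(names(attrs), "patient_id"))
      if (is.character(attrs[[nm]]))
        attrs[[nm]] <- as.logical(attrs[[nm]])
    attrs <- attrs[attrs$patient_id %in% unique(records$patient_id), ,
                   drop = FALSE]
    summary_tbl <- summarize_cohort(attrs)
    paths$summary <- file.path(out_dir, "cohort_summary.csv")
    utils::write.csv(summary_tbl, paths$summary, row.names = FALSE)
    log_stage("cohort summary: ", nrow(summary_tbl), " attributes over ",
              attr(summary_tbl, "denominator"), " patients")
  }

  a <- config$analysis
  log_stage("two-segment analysis: split week ", a$split_week,
            ", fill ", a$fill)
  analysis <- run_two_phase_analysis(weekly, split_week = a$split_week,
                                     fill = a$fill, orders = a$orders,
                                     max_p = a$max_p, max_d = a$max_d,
                                     max_q = a$max_q, alpha = a$alpha,
                                     horizon = a$horizon, level = a$level)
  paths$analysis <- file.path(out_dir, "analysis_report.json")
  jsonlite::write_json(analysis_report(analysis), paths$analysis,
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  for (nm in names(analysis$segments)) {
    s <- analysis$segments[[nm]]
    log_stage(nm, ": ARIMA(", paste(s$order, collapse = ","),
              "), ADF p = ", format(s$adf$p_value, digits = 3L),
              ", Box-Pierce p = ", format(s$box_pierce$p_value, digits = 3L))
  }

  invisible(list(paths = paths, reports = reports, weekly = weekly,
                 summary = summary_tbl, analysis = analysis))
}

#' Flatten an analysis object into a serializable report
#'
#' @param analysis A `ua_analysis` object.
#' @return A plain nested list suitable for JSON serialization.
#' @export
analysis_report <- function(analysis) {
  stopifnot(inherits(analysis, "ua_analysis"))
  seg_report <- function(s) list(
    order = list(p = s$order[1L], d = s$order[2L], q = s$order[3L]),
    adf = list(statistic = s$adf$statistic, p_value = s$adf$p_value,
               lags = s$adf$lags_used,
               reject_unit_root = s$adf$reject_unit_root),
    coefficients = list(ar = s$fit$ar, ma = s$fit$ma,
                        intercept = s$fit$intercept),
    aic = s$fit$aic, loglik = s$fit$loglik,
    box_pierce = list(q_statistic = s$box_pierce$q_statistic,
                      df = s$box_pierce$df,
                      p_value = s$box_pierce$p_value,
                      n_lags = s$box_pierce$n_lags),
    forecast = as.data.frame(s$forecast))
  list(split_week = analysis$split_week, fill = analysis$fill,
       filled_weeks = analysis$filled_weeks, alpha = analysis$alpha,
       segments = lapply(analysis$segments, seg_report))
}
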