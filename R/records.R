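#' @keywords internal
"_PACKAGE"

#' Admissible urinalysis results
#'
#' The three outcomes a scheduled urinalysis occasion can have: a negative
#' test, a positive test, or a missed (scheduled but not taken) test. Any
#' other token in an input file is rejected.
#'
#' @format Character vector of length three.
#' @export
ua_results <- c("negative", "positive", "missed")

#' Construct a validated urinalysis record set
#'
#' A record set is a long-format data frame with one row per scheduled test
#' occasion and columns `patient_id` (character), `week` (integer,
#' patient-relative program week, 1-based) and `result` (one of
#' [ua_results]). Rows are sorted by patient then week; the program length
#' is carried as an attribute so downstream weekly aggregation knows the
#' full week range.
#'
#' @param x Data frame with columns `patient_id`, `week`, `result`.
#' @param program_length Length of the treatment program in weeks; every
#'   `week` must lie in `[1, program_length]`.
#' @return `x`, validated and sorted, with class `ua_records` and attribute
#'   `program_length`.
#' @export
as_ua_records <- function(x, program_length = 52L) {
  stopifnot(is.data.frame(x))
  if (length(program_length) != 1L || is.na(program_length) ||
      program_length < 1 || program_length != floor(program_length))
    stop("`program_length` must be a single integer >= 1", call. = FALSE)
  program_length <- as.integer(program_length)

  required <- c("patient_id", "week", "result")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  x <- x[required]
  x$patient_id <- as.character(x$patient_id)
  x$result <- as.character(x$result)

  bad_result <- which(!(x$result %in% ua_results))
  if (length(bad_result))
    stop("unknown result token(s) ",
         paste0("'", unique(x$result[bad_result]), "'", collapse = ", "),
         " in row(s) ", paste(utils::head(bad_result, 5L), collapse = ", "),
         " (admissible: ", paste(ua_results, collapse = ", "), ")",
         call. = FALSE)

  week_num <- suppressWarnings(as.numeric(x$week))
  bad_week <- which(is.na(week_num) | week_num != floor(week_num) |
                      week_num < 1 | week_num > program_length)
  if (length(bad_week))
    stop("week out of [1, ", program_length, "] or non-integer in row(s) ",
         paste(utils::head(bad_week, 5L), collapse = ", "), call. = FALSE)
  x$week <- as.integer(week_num)

  key <- paste(x$patient_id, x$week, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicate (patient_id, week) pair(s), e.g. patient '",
         x$patient_id[dup[1L]], "' week ", x$week[dup[1L]], call. = FALSE)

  x <- x[order(x$patient_id, x$week), , drop = FALSE]
  rownames(x) <- NULL
  structure(x, program_length = program_length,
            class = c("ua_records", "data.frame"))
}

#' Read urinalysis records from CSV
#'
#' Reads a long-format CSV (header mandatory; columns `patient_id`, `week`,
#' `result`; lowercase result tokens) and validates it into a `ua_records`
#' object. One row per test occasion; a `missed` row is an explicit record
#' of a scheduled-but-skipped test. Weeks are patient-relative: week 1 is a
#' patient's first program week.
#'
#' @param path Path to the CSV file.
#' @param program_length Program length in weeks (default 52).
#' @return A `ua_records` data frame, sorted by patient then week.
#' @seealso [write_records()] for the inverse operation.
#' @export
read_records <- function(path, program_length = 52L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character",
                        stringsAsFactors = FALSE)
  if (nrow(df) == 0L)
    df <- data.frame(patient_id = character(), week = integer(),
                     result = character(), stringsAsFactors = FALSE)
  as_ua_records(df, program_length = program_length)
}

#' Write urinalysis records to CSV
#'
#' Writes a record set in the same CSV dialect [read_records()] reads, so
#' that a write/read round trip reproduces the data field-exactly. Records
#' are written sorted by patient then week.
#'
#' @param records A `ua_records` object (or coercible data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  if (!inherits(records, "ua_records"))
    records <- as_ua_records(records)
  utils::write.csv(as.data.frame(records)[c("patient_id", "week", "result")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Program length of a record set
#' @param records A `ua_records` object.
#' @return Integer program length in weeks.
#' @export
program_length <- function(records) {
  pl <- attr(records, "program_length")
  if (is.null(pl)) 52L else pl
}

#' @export
print.ua_records <- function(x, ...) {
  cat("Urinalysis records: ", nrow(x), " occasions, ",
      length(unique(x$patient_id)), " patients, program length ",
      program_length(x), " weeks\n", sep = "")
  NextMethod()
}
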