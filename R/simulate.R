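#' Treatment-protocol constants
#'
#' The two-phase urinalysis protocol: testing every
#' `high_demand_interval` weeks (biweekly by default) until
#' `stabilization_threshold` negative samples have accumulated since the
#' last positive, then every `low_demand_interval` weeks (monthly, modeled
#' as every 4 weeks on the integer week grid). A positive result in either
#' phase returns the patient to high-demand testing and resets the
#' stabilization count. A missed appointment delays the next test by
#' `miss_delay` weeks (schedule drift), leaving phase and count unchanged.
#'
#' @param program_length Program length in weeks (default 52).
#' @param high_demand_interval Weeks between tests in the high-demand
#'   phase (default 2).
#' @param low_demand_interval Weeks between tests in the low-demand phase
#'   (default 4).
#' @param stabilization_threshold Negative samples required to enter the
#'   low-demand phase (default 4).
#' @param split_week First week of the second analysis segment
#'   (default 27).
#' @param miss_delay Schedule drift per missed appointment, in weeks
#'   (default 1).
#' @return A validated list of class `ua_protocol`.
#' @export
protocol_config <- function(program_length = 52L, high_demand_interval = 2L,
                            low_demand_interval = 4L,
                            stabilization_threshold = 4L, split_week = 27L,
                            miss_delay = 1L) {
  p <- list(program_length = as.integer(program_length),
            high_demand_interval = as.integer(high_demand_interval),
            low_demand_interval = as.integer(low_demand_interval),
            stabilization_threshold = as.integer(stabilization_threshold),
            split_week = as.integer(split_week),
            miss_delay = as.integer(miss_delay))
  if (any(vapply(p, function(v) is.na(v) || v < 1, logical(1L))))
    stop("all protocol fields must be integers >= 1", call. = FALSE)
  if (p$split_week > p$program_length)
    stop("split_week must be <= program_length", call. = FALSE)
  structure(p, class = "ua_protocol")
}

#' Cohort-simulation parameters
#'
#' Generative settings for the synthetic cohort. The defaults emulate the
#' study conditions: 312 completers of a 52-week program, with relapse and
#' missed-appointment rates calibrated so the mean week of transition to
#' the low-demand phase (among patients who reach it within the program)
#' falls near the protocol's 6-month milestone.
#'
#' @param n_patients Number of patients (default 312).
#' @param p_positive_high Probability an attended high-demand test is
#'   positive (default 0.4).
#' @param p_positive_low Probability an attended low-demand test is
#'   positive (default 0.15).
#' @param p_missed Probability a scheduled test is missed (default 0.15).
#' @param p_dropout_per_occasion Probability the patient drops out after
#'   each occasion (default 0.01).
#' @param seed Master RNG seed; per-patient substreams are derived from it
#'   so cohorts are reproducible and order-independent.
#' @return A validated list of class `ua_simconfig`.
#' @export
simulation_config <- function(n_patients = 312L, p_positive_high = 0.4,
                              p_positive_low = 0.15, p_missed = 0.15,
                              p_dropout_per_occasion = 0.01, seed = 1L) {
  s <- list(n_patients = as.integer(n_patients),
            p_positive_high = p_positive_high,
            p_positive_low = p_positive_low, p_missed = p_missed,
            p_dropout_per_occasion = p_dropout_per_occasion,
            seed = as.integer(seed))
  probs <- unlist(s[c("p_positive_high", "p_positive_low", "p_missed",
                      "p_dropout_per_occasion")])
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (is.na(s$n_patients) || s$n_patients < 1)
    stop("n_patients must be >= 1", call. = FALSE)
  structure(s, class = "ua_simconfig")
}

#' Advance a patient's protocol state by one test occasion
#'
#' The protocol state machine. Given the state before a test occasion and
#' its outcome, returns the state afterwards: a negative in high demand
#' increments the stabilization count and, on reaching the threshold,
#' switches the patient to low demand; a positive in either phase returns
#' the patient to high demand with the count reset; a missed test changes
#' neither phase nor count but delays the next test by `miss_delay` weeks.
#' For attended tests the next test is scheduled one (post-transition)
#' phase interval ahead.
#'
#' @param state List with fields `phase` (`"high_demand"` or
#'   `"low_demand"`), `negatives` (stabilization count) and
#'   `next_test_week` (week of the occasion being resolved).
#' @param outcome One of [ua_results].
#' @param protocol A [protocol_config()] object.
#' @return The updated state list.
#' @export
step_patient <- function(state, outcome, protocol = protocol_config()) {
  stopifnot(outcome %in% ua_results,
            state$phase %in% c("high_demand", "low_demand"))
  if (outcome == "missed") {
    state$next_test_week <- state$next_test_week + protocol$miss_delay
    return(state)
  }
  if (outcome == "positive") {
    state$phase <- "high_demand"
    state$negatives <- 0L
  } else {                              # negative
    if (state$phase == "high_demand") {
      state$negatives <- state$negatives + 1L
      if (state$negatives >= protocol$stabilization_threshold) {
        state$phase <- "low_demand"
        state$negatives <- 0L
      }
    }
  }
  interval <- if (state$phase == "high_demand") protocol$high_demand_interval
              else protocol$low_demand_interval
  state$next_test_week <- state$next_test_week + interval
  state
}

#' Simulate one patient trajectory
#'
#' Draws a single trajectory from the protocol state machine using the
#' current RNG stream. The first test is scheduled at week
#' `high_demand_interval`; at each occasion the test is missed with
#' probability `p_missed`, otherwise positive with the current phase's
#' positive rate; after each occasion the patient drops out with
#' probability `p_dropout_per_occasion`. The trajectory ends at dropout or
#' when the next scheduled test falls beyond `program_length`.
#'
#' @param protocol A [protocol_config()].
#' @param sim A [simulation_config()] (the seed field is ignored here; the
#'   caller owns the RNG state).
#' @param patient_id Identifier for the generated patient.
#' @return Data frame of records (`patient_id`, `week`, `result`) with
#'   attribute `transition_week`: the week of the test on which the
#'   patient first entered the low-demand phase (`NA` if never).
#' @export
simulate_patient <- function(protocol = protocol_config(),
                             sim = simulation_config(),
                             patient_id = "P1") {
  week <- protocol$high_demand_interval
  state <- list(phase = "high_demand", negatives = 0L,
                next_test_week = week)
  weeks <- integer()
  results <- character()
  transition <- NA_integer_
  while (week <= protocol$program_length) {
    if (stats::runif(1L) < sim$p_missed) {
      outcome <- "missed"
    } else {
      p_pos <- if (state$phase == "high_demand") sim$p_positive_high
               else sim$p_positive_low
      outcome <- if (stats::runif(1L) < p_pos) "positive" else "negative"
    }
    weeks <- c(weeks, week)
    results <- c(results, outcome)
    was_high <- state$phase == "high_demand"
    state <- step_patient(state, outcome, protocol)
    if (was_high && state$phase == "low_demand" && is.na(transition))
      transition <- week
    if (stats::runif(1L) < sim$p_dropout_per_occasion) break
    week <- state$next_test_week
  }
  structure(data.frame(patient_id = patient_id, week = weeks,
                       result = results, stringsAsFactors = FALSE),
            transition_week = transition)
}

#' Simulate a synthetic cohort
#'
#' Draws `n_patients` independent trajectories. A per-patient seed is
#' derived deterministically from the master seed, so the cohort is
#' reproducible and each patient's trajectory does not depend on how many
#' patients precede it.
#'
#' @param protocol A [protocol_config()].
#' @param sim A [simulation_config()]; `sim$seed` is the master seed.
#' @return A `ua_records` object with attribute `transition_weeks` (one
#'   value per patient, `NA` for patients who never stabilized).
#' @export
simulate_cohort <- function(protocol = protocol_config(),
                            sim = simulation_config()) {
  set.seed(sim$seed)
  patient_seeds <- sample.int(.Machine$integer.max, sim$n_patients)
  width <- nchar(as.character(sim$n_patients))
  ids <- sprintf(paste0("P%0", width, "d"), seq_len(sim$n_patients))
  parts <- vector("list", sim$n_patients)
  transitions <- integer(sim$n_patients)
  for (i in seq_len(sim$n_patients)) {
    set.seed(patient_seeds[i])
    parts[[i]] <- simulate_patient(protocol, sim, patient_id = ids[i])
    transitions[i] <- attr(parts[[i]], "transition_week")
  }
  out <- as_ua_records(do.call(rbind, parts),
                       program_length = protocol$program_length)
  attr(out, "transition_weeks") <- transitions
  out
}
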