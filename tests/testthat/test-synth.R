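test_that("state machine handles stabilization, relapse and missed tests", {
  p <- protocol_config()
  s <- list(phase = "high_demand", negatives = 3L, next_test_week = 8L)
  # fourth negative triggers the phase switch and resets the counter
  after <- step_patient(s, "negative", p)
  expect_equal(after$phase, "low_demand")
  expect_equal(after$negatives, 0L)
  expect_equal(after$next_test_week, 12L)  # new phase's monthly interval
  # positive in low demand returns to biweekly with a reset counter
  low <- list(phase = "low_demand", negatives = 0L, next_test_week = 20L)
  back <- step_patient(low, "positive", p)
  expect_equal(back$phase, "high_demand")
  expect_equal(back$negatives, 0L)
  expect_equal(back$next_test_week, 22L)
  # missed: phase and counter unchanged, schedule drifts by one week
  for (st in list(s, low)) {
    m <- step_patient(st, "missed", p)
    expect_equal(m$phase, st$phase)
    expect_equal(m$negatives, st$negatives)
    expect_equal(m$next_test_week, st$next_test_week + 1L)
  }
  # negative below threshold only increments the counter
  early <- step_patient(list(phase = "high_demand", negatives = 1L,
                             next_test_week = 4L), "negative", p)
  expect_equal(early$phase, "high_demand")
  expect_equal(early$negatives, 2L)
  expect_equal(early$next_test_week, 6L)
})

test_that("all-negative patient follows the hand-traced schedule", {
  sim <- simulation_config(n_patients = 1, p_positive_high = 0,
                           p_positive_low = 0, p_missed = 0,
                           p_dropout_per_occasion = 0, seed = 1)
  set.seed(1)
  tr <- simulate_patient(protocol_config(), sim)
  # biweekly through stabilization at week 8, then monthly
  expect_equal(tr$week, c(2, 4, 6, 8, seq(12, 52, 4)))
  expect_equal(attr(tr, "transition_week"), 8L)
  expect_true(all(tr$result == "negative"))
})

test_that("immediate dropout yields exactly one occasion", {
  sim <- simulation_config(n_patients = 1, p_dropout_per_occasion = 1,
                           seed = 1)
  set.seed(1)
  expect_equal(nrow(simulate_patient(protocol_config(), sim)), 1L)
})

test_that("cohorts are reproducible under a seed and differ across seeds", {
  sim <- simulation_config(n_patients = 25, seed = 42)
  a <- simulate_cohort(protocol_config(), sim)
  b <- simulate_cohort(protocol_config(), sim)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(attr(a, "transition_weeks"), attr(b, "transition_weeks"))
  sim2 <- simulation_config(n_patients = 25, seed = 43)
  c <- simulate_cohort(protocol_config(), sim2)
  expect_false(identical(as.data.frame(a), as.data.frame(c)))
})

test_that("deterministic all-negative cohort gives identical schedules", {
  sim <- simulation_config(n_patients = 20, p_positive_high = 0,
                           p_positive_low = 0, p_missed = 0,
                           p_dropout_per_occasion = 0, seed = 5)
  rec <- simulate_cohort(protocol_config(), sim)
  sched <- tapply(rec$week, rec$patient_id, function(w)
    paste(w, collapse = ","))
  expect_equal(length(unique(sched)), 1L)
  expect_equal(attr(rec, "transition_weeks"), rep(8L, 20))
})

test_that("without misses high-demand tests land on even weeks; misses drift", {
  p <- protocol_config()
  no_miss <- simulate_cohort(p, simulation_config(
    n_patients = 100, p_missed = 0, p_dropout_per_occasion = 0, seed = 31))
  tw <- attr(no_miss, "transition_weeks")
  # before transition every test is in high demand: even weeks only
  for (id in unique(no_miss$patient_id)) {
    i <- match(id, unique(no_miss$patient_id))
    hd <- no_miss$week[no_miss$patient_id == id &
                         (is.na(tw[i]) | no_miss$week <= tw[i])]
    expect_true(all(hd %% 2 == 0))
  }

  # with misses, the odd-week share of tests rises over week blocks
  drift <- simulate_cohort(p, simulation_config(
    n_patients = 500, p_missed = 0.2, p_dropout_per_occasion = 0,
    seed = 32))
  blocks <- cut(drift$week, c(0, 13, 26, 39, 52))
  odd_share <- tapply(drift$week %% 2 == 1, blocks, mean)
  expect_true(all(diff(odd_share) > 0) || odd_share[4] > odd_share[1])
  expect_true(odd_share[1] < odd_share[4])
})

test_that("stabilization takes exactly the threshold count of negatives", {
  p <- protocol_config(stabilization_threshold = 6)
  sim <- simulation_config(n_patients = 1, p_positive_high = 0,
                           p_positive_low = 0, p_missed = 0,
                           p_dropout_per_occasion = 0, seed = 1)
  set.seed(1)
  tr <- simulate_patient(p, sim)
  expect_equal(attr(tr, "transition_week"), 12L)  # 6 biweekly tests
})

test_that("transition week is stochastically nondecreasing in relapse and miss rates", {
  mean_transition <- function(p_pos, p_miss, seed) {
    sim <- simulation_config(n_patients = 1000, p_positive_high = p_pos,
                             p_missed = p_miss,
                             p_dropout_per_occasion = 0, seed = seed)
    mean(attr(simulate_cohort(protocol_config(), sim), "transition_weeks"),
         na.rm = TRUE)
  }
  expect_gt(mean_transition(0.3, 0.15, 51), 8)
  expect_gt(mean_transition(0.3, 0.15, 52), mean_transition(0.05, 0.15, 52))
  expect_gt(mean_transition(0.2, 0.3, 53), mean_transition(0.2, 0.0, 53))
})

test_that("simulated cohorts run the full scoring and analysis pipeline", {
  rec <- simulate_cohort(protocol_config(),
                         simulation_config(n_patients = 150, seed = 77))
  w <- group_weekly_scores(rec)
  expect_equal(nrow(w), 52L)
  an <- run_two_phase_analysis(w)
  for (seg in an$segments) {
    expect_s3_class(seg$fit, "ua_arima")
    expect_true(is.finite(seg$box_pierce$p_value))
    expect_equal(nrow(seg$forecast), 8L)
  }
})
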