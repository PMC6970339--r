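# Fixture builders and independent brute-force oracles shared across tests.

make_records <- function(patient_id, week, result, program_length = 52L) {
  as_ua_records(data.frame(patient_id = patient_id, week = week,
                           result = result, stringsAsFactors = FALSE),
                program_length = program_length)
}

# Random valid dataset: a handful of patients, distinct weeks per patient.
random_records <- function(max_records = 200L, program_length = 52L) {
  n_pat <- sample(1:8, 1L)
  parts <- lapply(seq_len(n_pat), function(i) {
    n <- sample(0:min(program_length, ceiling(max_records / n_pat)), 1L)
    if (n == 0L) return(NULL)
    data.frame(patient_id = paste0("pt", i),
               week = sort(sample.int(program_length, n)),
               result = sample(ua_results, n, replace = TRUE),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, parts)
  if (is.null(df))
    df <- data.frame(patient_id = character(), week = integer(),
                     result = character(), stringsAsFactors = FALSE)
  as_ua_records(df, program_length = program_length)
}

# Brute-force weekly aggregation: loops over records one at a time,
# independent of the vectorized implementation.
brute_weekly <- function(records, program_length) {
  score <- integer(program_length)
  n <- integer(program_length)
  for (r in seq_len(nrow(records))) {
    w <- records$week[r]
    res <- records$result[r]
    score[w] <- score[w] + switch(res, negative = 1L, positive = -1L,
                                  missed = 0L)
    if (res != "missed") n[w] <- n[w] + 1L
  }
  list(score = score, n = n,
       adjusted = ifelse(n > 0, score / n, NA_real_))
}

# Brute-force Box-Pierce statistic from first principles.
brute_box_pierce_q <- function(x, n_lags) {
  T <- length(x)
  xc <- x - mean(x)
  denom <- sum(xc^2)
  rho <- vapply(seq_len(n_lags), function(k)
    sum(xc[seq_len(T - k)] * xc[(k + 1):T]) / denom, numeric(1))
  T * sum(rho^2)
}
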