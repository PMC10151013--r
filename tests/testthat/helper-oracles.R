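# Independent oracles and fixture builders used across the suite. These stay
# deliberately naive (dense grids, direct formulas) so they cannot share a
# defect with the implementation paths they check.

# Dense fixed-grid (trapezoid, log-space) integration oracle for the marginal
# log-likelihood of the random-intercept logistic model.
oracle_marginal_loglik <- function(y, X, group, gamma, sigma_u,
                                   half_width = 12, n_grid = 20001L) {
  eta0 <- drop(as.matrix(X) %*% gamma)
  u <- seq(-half_width * sigma_u, half_width * sigma_u, length.out = n_grid)
  du <- u[2] - u[1]
  total <- 0
  for (j in unique(group)) {
    idx <- which(group == j)
    lg <- vapply(u, function(uu) {
      eta <- eta0[idx] + uu
      sum(y[idx] * eta - log1p(exp(eta))) + dnorm(uu, 0, sigma_u, log = TRUE)
    }, numeric(1))
    m <- max(lg)
    total <- total + m + log(sum(exp(lg - m)) * du)
  }
  total
}

# Spearman rho by the direct rank formula (no ties): 1 - 6*sum(d^2)/(n(n^2-1))
oracle_spearman_noties <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Hand-built device log: one configuration/frequency unless overridden.
make_log <- function(R, X = -0.05 * R, t0 = as.POSIXct("2026-01-05 08:00:00", tz = "UTC"),
                     interval_s = 150, configuration = "long",
                     frequency = 128, battery = NULL, participant = "T01",
                     reported_days = 1L, selftests = NULL) {
  n <- length(R)
  if (is.null(battery)) battery <- seq(4.2, 3.6, length.out = n)
  samples <- data.frame(
    timestamp = t0 + (seq_len(n) - 1L) * interval_s,
    configuration = configuration, frequency_khz = frequency,
    resistance_ohm = R, reactance_ohm = X, battery_v = battery,
    stringsAsFactors = FALSE)
  if (is.null(selftests))
    selftests <- data.frame(session_index = 1L, frequency_khz = frequency,
                            nominal_ohm = 100, measured_ohm = 100)
  device_log(participant, samples, selftests, reported_days)
}

# ESM reports table for one participant from call clock-hours per day.
make_reports <- function(hours_by_day, participant = "T01",
                         date0 = as.Date("2026-01-05"), answered = NULL,
                         momentary = NULL) {
  rows <- list()
  for (d in seq_along(hours_by_day)) {
    h <- hours_by_day[[d]]
    ts <- as.POSIXct(paste(date0 + (d - 1), "00:00:00"), tz = "UTC") + h * 3600
    rows[[d]] <- data.frame(
      participant_id = participant, day = d, call_index = seq_along(h),
      timestamp = ts, answered = TRUE, momentary_pain = 0L,
      pain_since_last = "no", stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (!is.null(answered)) out$answered <- answered
  if (!is.null(momentary)) out$momentary_pain <- momentary
  out
}

# Small reference synthetic cohort reused by the GLMM tests (built once).
reference_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_reduced_cohort(n_participants = 60, seed = 7)$reduced
    cache
  }
})
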