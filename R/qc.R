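# Ordered decision-tree artifact classifier. Checks are applied in order:
# session/day alignment -> on-board self-test -> phase band -> resistance
# band -> per-call-period clean fraction -> per-day 3-of-4 rule. A "no" at
# any step classifies the affected scope as artifact; earlier failures
# short-circuit later checks. All range bounds are strict inequalities, so
# boundary values are artifacts.

#' QC configuration
#'
#' Defaults encode the acceptance bands of the decision tree: phase in
#' (-50, 0) degrees, resistance in (0, 212) ohm, a call period needs strictly
#' more than 25% artifact-free data, and at least 3 of a day's 4 call periods
#' must meet that fraction or the whole day is dropped.
#'
#' @param selftest_tolerance relative self-test tolerance (default 0.10)
#' @param phase_min,phase_max phase acceptance band, degrees (strict)
#' @param resistance_min,resistance_max resistance band, ohm (strict)
#' @param min_period_clean_fraction minimum clean fraction per period (strict)
#' @param min_valid_periods_per_day day rule threshold (default 3)
#' @param periods_per_day scheduled call periods per day (default 4)
#' @param require_session_day_alignment drop everything when the battery
#'   discharge event count disagrees with reported wear days (default TRUE)
#' @param alignment_tolerance allowed |sessions - reported days| (default 0)
#' @return a `qc_config` list
#' @export
qc_config <- function(selftest_tolerance = 0.10,
                      phase_min = -50, phase_max = 0,
                      resistance_min = 0, resistance_max = 212,
                      min_period_clean_fraction = 0.25,
                      min_valid_periods_per_day = 3L,
                      periods_per_day = 4L,
                      require_session_day_alignment = TRUE,
                      alignment_tolerance = 0L) {
  check_that(phase_min < phase_max, "phase_min", "phase_min < phase_max required")
  check_that(resistance_min < resistance_max, "resistance_min",
             "resistance_min < resistance_max required")
  check_that(min_period_clean_fraction > 0 && min_period_clean_fraction < 1,
             "min_period_clean_fraction", "must lie strictly in (0,1)")
  structure(list(selftest_tolerance = selftest_tolerance,
                 phase_min = phase_min, phase_max = phase_max,
                 resistance_min = resistance_min,
                 resistance_max = resistance_max,
                 min_period_clean_fraction = min_period_clean_fraction,
                 min_valid_periods_per_day = as.integer(min_valid_periods_per_day),
                 periods_per_day = as.integer(periods_per_day),
                 require_session_day_alignment = require_session_day_alignment,
                 alignment_tolerance = as.integer(alignment_tolerance)),
            class = "qc_config")
}

#' Check battery-event / reported-wear-day alignment
#'
#' Passes iff the number of distinguishable battery discharge sessions equals
#' the participant's reported number of wear days (within
#' `alignment_tolerance`, default exact).
#'
#' @param sessions output of [segment_sessions()]
#' @param reported_wear_days reported wear-day count (NA skips the check with
#'   a warning)
#' @param config a [qc_config()]
#' @return TRUE/FALSE (NA reported days return TRUE with a warning)
#' @export
check_day_alignment <- function(sessions, reported_wear_days,
                                config = qc_config()) {
  if (is.na(reported_wear_days)) {
    warning("reported_wear_days missing; skipping day-alignment check")
    return(TRUE)
  }
  abs(nrow(sessions) - reported_wear_days) <= config$alignment_tolerance
}

#' Sample-level artifact classification
#'
#' A sample is clean iff its session passed day alignment and the self-test,
#' its phase angle lies strictly inside the phase band, and its resistance
#' lies strictly inside the resistance band. Classification is per
#' (timestamp, configuration, frequency): one frequency failing does not
#' remove other frequencies at the same epoch. Each dropped sample carries the
#' single reason code of the first check it failed, in tree order.
#'
#' @param log a [device_log()]
#' @param sessions output of [segment_sessions()]
#' @param config a [qc_config()]
#' @return a `qc_report`: list with `samples` (data.frame: `clean`, `reason`),
#'   `session_pass` (logical per session), `alignment_pass`, and `summary`
#'   counts
#' @export
classify_samples <- function(log, sessions, config = qc_config()) {
  s <- log$samples
  n <- nrow(s)
  sample_sess <- attr(sessions, "sample_session")
  align_ok <- check_day_alignment(sessions, log$reported_wear_days, config)
  st_ok <- check_selftest(log, sessions, tolerance = config$selftest_tolerance)
  reason <- rep(NA_character_, n)
  clean <- rep(TRUE, n)
  if (!align_ok && config$require_session_day_alignment) {
    clean[] <- FALSE
    reason[] <- "day_misalignment"
  } else {
    sess_fail <- !st_ok[sample_sess]
    clean[sess_fail] <- FALSE
    reason[sess_fail] <- "selftest_fail"
    todo <- clean
    phase_bad <- todo & !(s$phase_deg > config$phase_min &
                            s$phase_deg < config$phase_max)
    clean[phase_bad] <- FALSE
    reason[phase_bad] <- "phase_out_of_band"
    todo <- clean
    res_bad <- todo & !(s$resistance_ohm > config$resistance_min &
                          s$resistance_ohm < config$resistance_max)
    clean[res_bad] <- FALSE
    reason[res_bad] <- "resistance_out_of_band"
  }
  structure(list(
    samples = data.frame(clean = clean, reason = reason,
                         stringsAsFactors = FALSE),
    session_pass = st_ok & (align_ok || !config$require_session_day_alignment),
    alignment_pass = align_ok,
    summary = c(total = n, kept = sum(clean), dropped = sum(!clean))
  ), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: %d samples, %d kept, %d dropped\n",
              x$summary["total"], x$summary["kept"], x$summary["dropped"]))
  if (x$summary["dropped"] > 0)
    print(table(x$samples$reason[!x$samples$clean]))
  invisible(x)
}

#' Per-call-period and per-day filtering
#'
#' A period is kept iff its clean fraction (clean samples / total assigned
#' samples, for the relevant electrode configuration) strictly exceeds
#' `min_period_clean_fraction`; additionally all of a day's periods are
#' dropped when fewer than `min_valid_periods_per_day` of that day's answered
#' periods meet the fraction test. Days with fewer answered periods than
#' scheduled apply the day rule as at least
#' `min(min_valid_periods_per_day, answered)` qualifying periods (flagged in
#' the output). Periods with zero assigned samples are dropped with reason
#' `empty_period`.
#'
#' @param periods data.frame with columns `participant_id`, `day`,
#'   `call_index`, `n_total`, `n_clean` (one row per answered call period for
#'   one electrode configuration)
#' @param config a [qc_config()]
#' @return `periods` with added columns `clean_fraction`, `kept`, `reason`,
#'   `day_rule_relaxed`
#' @export
filter_call_periods <- function(periods, config = qc_config()) {
  p <- periods
  p$clean_fraction <- ifelse(p$n_total > 0, p$n_clean / p$n_total, 0)
  qualifies <- p$n_total > 0 & p$clean_fraction > config$min_period_clean_fraction
  key <- paste(p$participant_id, p$day)
  answered_per_day <- stats::ave(rep(1L, nrow(p)), key, FUN = sum)
  need <- pmin(config$min_valid_periods_per_day, answered_per_day)
  qual_per_day <- stats::ave(as.integer(qualifies), key, FUN = sum)
  day_ok <- qual_per_day >= need
  p$kept <- qualifies & day_ok
  p$reason <- NA_character_
  p$reason[!p$kept & day_ok & p$n_total == 0] <- "empty_period"
  p$reason[!p$kept & day_ok & p$n_total > 0] <- "period_clean_fraction"
  p$reason[!day_ok] <- "day_rule"
  p$day_rule_relaxed <- answered_per_day < config$periods_per_day
  p
}

#' Run the complete decision tree for one participant
#'
#' Convenience wrapper: segments sessions, classifies samples, assigns clean
#' samples to ESM call-period windows (per configuration, independently),
#' applies the period/day rules, and returns everything needed for feature
#' reduction.
#'
#' @param log a [device_log()]
#' @param reports ESM reports for this participant (see [window_samples()])
#' @param config a [qc_config()]
#' @param gap_threshold,recharge_jump session segmentation controls
#' @return list with `sessions`, `qc` (the sample-level `qc_report`),
#'   `periods` (windowed call periods with keep/drop decisions per
#'   configuration), and `assignment` (per-sample period id or NA)
#' @export
qc_pipeline <- function(log, reports, config = qc_config(),
                        gap_threshold = 120, recharge_jump = 0.2) {
  sessions <- segment_sessions(log, gap_threshold, recharge_jump)
  qc <- classify_samples(log, sessions, config)
  win <- window_samples(log$samples, reports)
  s <- log$samples
  per_cfg <- lapply(c("long", "trans"), function(cfg) {
    idx <- which(s$configuration == cfg)
    fpid <- factor(win$assignment[idx], levels = seq_len(nrow(win$periods)))
    n_total <- as.integer(table(fpid))
    n_clean <- as.integer(table(fpid[qc$samples$clean[idx]]))
    pd <- cbind(win$periods, config = cfg, n_total = n_total, n_clean = n_clean)
    filter_call_periods(pd, config)
  })
  periods <- do.call(rbind, per_cfg)
  rownames(periods) <- NULL
  list(sessions = sessions, qc = qc, periods = periods,
       win_periods = win$periods, assignment = win$assignment)
}
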