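# Device-log ingestion: parse the CSV dialect written by the wearable's
# post-processing chain, segment logs into battery-discharge wear sessions,
# and verify the on-board impedance self-test.

#' Construct a device log object
#'
#' @param participant_id identifier
#' @param samples data.frame with columns `timestamp` (POSIXct),
#'   `configuration` ("long"/"trans"), `frequency_khz`, `resistance_ohm`,
#'   `reactance_ohm`, `battery_v`; a `phase_deg` column is (re)computed
#' @param selftests data.frame with columns `session_index`, `frequency_khz`,
#'   `nominal_ohm`, `measured_ohm` (may be empty)
#' @param reported_wear_days participant-reported number of wear days (or NA)
#' @return a `device_log` object
#' @export
device_log <- function(participant_id, samples, selftests = NULL,
                       reported_wear_days = NA_integer_) {
  need <- c("timestamp", "configuration", "frequency_khz",
            "resistance_ohm", "reactance_ohm", "battery_v")
  miss <- setdiff(need, names(samples))
  if (length(miss))
    stop("samples missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  ord <- order(samples$timestamp, samples$configuration, samples$frequency_khz)
  samples <- samples[ord, , drop = FALSE]
  key <- paste(format_ts(samples$timestamp), samples$configuration,
               samples$frequency_khz)
  if (anyDuplicated(key))
    stop("duplicate (timestamp, configuration, frequency) keys in samples",
         call. = FALSE)
  samples$phase_deg <- phase_deg(samples$resistance_ohm, samples$reactance_ohm)
  if (is.null(samples$artifact_flag))
    samples$artifact_flag <- rep("unclassified", nrow(samples))
  rownames(samples) <- NULL
  if (is.null(selftests))
    selftests <- data.frame(session_index = integer(), frequency_khz = numeric(),
                            nominal_ohm = numeric(), measured_ohm = numeric())
  structure(list(participant_id = participant_id, samples = samples,
                 selftests = selftests,
                 reported_wear_days = reported_wear_days),
            class = "device_log")
}

#' @export
print.device_log <- function(x, ...) {
  cat(sprintf("device_log: participant %s, %d samples, %d self-test records\n",
              x$participant_id, nrow(x$samples), nrow(x$selftests)))
  invisible(x)
}

#' Read a device log CSV
#'
#' Dialect: header `timestamp,configuration,frequency_khz,resistance_ohm,
#' reactance_ohm,battery_v`, ISO-8601 timestamps, configuration in
#' `{long, trans}`, UTF-8, LF line endings. Malformed rows are rejected and
#' counted rather than silently dropped; more than `malformed_tol` malformed
#' rows (default 1%) is an integrity error.
#'
#' @param path CSV file path
#' @param participant_id identifier to attach
#' @param selftest_path optional self-test CSV
#'   (`session_index,frequency_khz,nominal_ohm,measured_ohm`)
#' @param reported_wear_days participant-reported wear days
#' @param malformed_tol maximum tolerated fraction of malformed rows
#' @return a [device_log()]; the number of rejected rows is attached as
#'   attribute `n_malformed`
#' @export
read_device_log <- function(path, participant_id, selftest_path = NULL,
                            reported_wear_days = NA_integer_,
                            malformed_tol = 0.01) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  need <- c("timestamp", "configuration", "frequency_khz", "resistance_ohm",
            "reactance_ohm", "battery_v")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("device log missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  n <- nrow(raw)
  ts <- parse_ts(raw$timestamp)
  num <- function(x) suppressWarnings(as.numeric(x))
  R <- num(raw$resistance_ohm); X <- num(raw$reactance_ohm)
  f <- num(raw$frequency_khz); bv <- num(raw$battery_v)
  ok <- !is.na(ts) & !is.na(R) & !is.na(X) & !is.na(f) & !is.na(bv) &
    raw$configuration %in% c("long", "trans")
  n_bad <- sum(!ok)
  if (n > 0 && n_bad / n > malformed_tol)
    stop(sprintf("integrity error: %d of %d rows malformed (> %.1f%% tolerated)",
                 n_bad, n, 100 * malformed_tol), call. = FALSE)
  samples <- data.frame(timestamp = ts[ok], configuration = raw$configuration[ok],
                        frequency_khz = f[ok], resistance_ohm = R[ok],
                        reactance_ohm = X[ok], battery_v = bv[ok],
                        stringsAsFactors = FALSE)
  selftests <- NULL
  if (!is.null(selftest_path)) {
    selftests <- utils::read.csv(selftest_path)
    needst <- c("session_index", "frequency_khz", "nominal_ohm", "measured_ohm")
    missst <- setdiff(needst, names(selftests))
    if (length(missst))
      stop("self-test file missing column(s): ",
           paste(missst, collapse = ", "), call. = FALSE)
    if (any(selftests$nominal_ohm <= 0))
      stop("self-test nominal impedance must be positive", call. = FALSE)
  }
  log <- device_log(participant_id, samples, selftests, reported_wear_days)
  attr(log, "n_malformed") <- n_bad
  log
}

#' Write a device log CSV in the canonical dialect
#'
#' Timestamps are written to 1 s and impedances to 1e-3 ohm, the round-trip
#' resolution of the format.
#'
#' @param log a [device_log()]
#' @param path output CSV path
#' @param selftest_path optional output path for the self-test CSV
#' @return `path`, invisibly
#' @export
write_device_log <- function(log, path, selftest_path = NULL) {
  s <- log$samples
  out <- data.frame(timestamp = format_ts(s$timestamp),
                    configuration = s$configuration,
                    frequency_khz = s$frequency_khz,
                    resistance_ohm = sprintf("%.3f", s$resistance_ohm),
                    reactance_ohm = sprintf("%.3f", s$reactance_ohm),
                    battery_v = sprintf("%.3f", s$battery_v))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  if (!is.null(selftest_path))
    utils::write.csv(log$selftests, selftest_path, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Segment a device log into battery-discharge wear sessions
#'
#' A new session starts whenever the gap between consecutive sample epochs
#' exceeds `gap_threshold` minutes, or the battery voltage increases by more
#' than `recharge_jump` volts between consecutive epochs (a recharge event).
#' These two rules operationalise "distinguishable battery discharge events".
#'
#' @param log a [device_log()]
#' @param gap_threshold minutes of silence that split sessions (default 120)
#' @param recharge_jump volts of battery increase that split sessions
#'   (default 0.2)
#' @return data.frame with one row per session (`session_index`, `start`,
#'   `end`, `n_epochs`, `n_samples`); the per-sample session index is attached
#'   as attribute `sample_session`
#' @export
segment_sessions <- function(log, gap_threshold = 120, recharge_jump = 0.2) {
  s <- log$samples
  if (nrow(s) == 0L) {
    out <- data.frame(session_index = integer(), start = as.POSIXct(character()),
                      end = as.POSIXct(character()), n_epochs = integer(),
                      n_samples = integer())
    attr(out, "sample_session") <- integer()
    return(out)
  }
  ep_ts <- sort(unique(s$timestamp))
  ep_bv <- s$battery_v[match(ep_ts, s$timestamp)]
  dt_min <- c(0, diff(as.numeric(ep_ts)) / 60)
  dbv <- c(0, diff(ep_bv))
  new_session <- dt_min > gap_threshold | dbv > recharge_jump
  sess <- cumsum(new_session) + 1L
  sample_sess <- sess[match(s$timestamp, ep_ts)]
  out <- data.frame(
    session_index = seq_len(max(sess)),
    start = as.POSIXct(tapply(as.numeric(ep_ts), sess, min),
                       origin = "1970-01-01", tz = "UTC"),
    end = as.POSIXct(tapply(as.numeric(ep_ts), sess, max),
                     origin = "1970-01-01", tz = "UTC"),
    n_epochs = as.integer(tabulate(sess)),
    n_samples = as.integer(tabulate(sample_sess, nbins = max(sess)))
  )
  attr(out, "sample_session") <- sample_sess
  out
}

#' Verify on-board self-test records per session
#'
#' A session passes iff every tested frequency has
#' `|measured - nominal| / nominal <= tolerance` (boundary inclusive,
#' default 10%). Sessions without any self-test record fail by default.
#'
#' @param log a [device_log()]
#' @param sessions output of [segment_sessions()]
#' @param tolerance relative tolerance in (0, 1), default 0.10
#' @param missing what to do for sessions with no record: `"fail"` (default)
#'   or `"pass"`
#' @return logical vector, one pass/fail per session
#' @export
check_selftest <- function(log, sessions, tolerance = 0.10,
                           missing = c("fail", "pass")) {
  missing <- match.arg(missing)
  stopifnot(tolerance > 0, tolerance < 1)
  st <- log$selftests
  vapply(sessions$session_index, function(i) {
    rec <- st[st$session_index == i, , drop = FALSE]
    if (nrow(rec) == 0L) return(missing == "pass")
    all(abs(rec$measured_ohm - rec$nominal_ohm) / rec$nominal_ohm <= tolerance)
  }, logical(1))
}
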