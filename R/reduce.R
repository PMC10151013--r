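# Feature reduction: assign cleaned samples to ESM call-period windows,
# transform to per-length values (PLR = R/L, PLX = X/L, in ohm/m), reduce each
# period to a mean and coefficient of variation, and screen redundant metrics
# with Spearman rank correlation.

#' Assign samples to ESM call-period windows
#'
#' Each answered ESM call owns the window (previous answered call of the same
#' day, this call], mirroring the "since the last phone call" question; the
#' first window of a day is anchored at the day's first logged sample
#' (left-closed). A sample exactly at a call timestamp belongs to that call's
#' period (right-closed). Samples after a day's last answered call are left
#' unassigned. An answered call with no samples in its window still gets a
#' (retained, empty) period for QC to drop.
#'
#' @param samples data.frame of samples for one participant (column
#'   `timestamp` required; other columns ignored)
#' @param reports ESM reports for the same participant: columns
#'   `participant_id`, `day`, `call_index`, `timestamp`, `answered`
#' @return list with `periods` (one row per answered call: `participant_id`,
#'   `day`, `call_index`, `window_start`, `window_end`) and `assignment`
#'   (integer per sample: row index into `periods`, or NA)
#' @export
window_samples <- function(samples, reports) {
  rep_ans <- reports[reports$answered, , drop = FALSE]
  rep_ans <- rep_ans[order(rep_ans$timestamp), , drop = FALSE]
  n <- nrow(samples)
  assignment <- rep(NA_integer_, n)
  sample_date <- as.Date(samples$timestamp, tz = "UTC")
  rep_date <- as.Date(rep_ans$timestamp, tz = "UTC")
  udays <- sort(unique(rep_date))
  periods <- NULL
  row_offset <- 0L
  for (di in seq_along(udays)) {
    d <- udays[di]
    day_rep <- rep_ans[rep_date == d, , drop = FALSE]
    cts <- day_rep$timestamp
    idx <- which(sample_date == d)
    day_start <- if (length(idx)) min(samples$timestamp[idx]) else cts[1]
    starts <- c(day_start, cts[-length(cts)])
    pd <- data.frame(participant_id = day_rep$participant_id,
                     day = day_rep$day, call_index = day_rep$call_index,
                     window_start = starts, window_end = cts)
    if (length(idx)) {
      j <- findInterval(as.numeric(samples$timestamp[idx]), as.numeric(cts),
                        left.open = TRUE) + 1L
      ok <- j <= length(cts)
      assignment[idx[ok]] <- row_offset + j[ok]
    }
    periods <- rbind(periods, pd)
    row_offset <- row_offset + nrow(pd)
  }
  if (is.null(periods))
    periods <- data.frame(participant_id = character(), day = integer(),
                          call_index = integer(),
                          window_start = as.POSIXct(character()),
                          window_end = as.POSIXct(character()))
  rownames(periods) <- NULL
  list(periods = periods, assignment = assignment)
}

#' Per-length impedance transform
#'
#' PLR = R / L and PLX = X / L, in ohm/m, where L is the distance between
#' voltage-sensing electrodes. Normalises impedance across knee sizes; the
#' sign of the reactance is preserved.
#'
#' @param value resistance or reactance in ohm (vectorised)
#' @param L electrode spacing in metres (> 0)
#' @return per-length value in ohm/m
#' @export
#' @examples
#' per_length(100, 0.25) # 400 ohm/m
per_length <- function(value, L) {
  if (any(L <= 0)) stop("electrode spacing L must be positive", call. = FALSE)
  value / L
}

#' Reduce a call period's values to mean and CV
#'
#' Mean is the arithmetic mean; CV is 100 x sample standard deviation (n-1
#' denominator) / |mean|, so negative-reactance periods still give positive
#' percentages. A period needs at least 2 values for a CV; with fewer the CV
#' is NA (and the period is excluded from models that use CV).
#'
#' @param values numeric vector of per-length values for one period
#' @return list with `mean`, `cv` (percent), `n`
#' @export
#' @examples
#' reduce_period(c(300, 400, 500)) # mean 400, cv 25
reduce_period <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0L) stop("reduction error: period has zero clean samples", call. = FALSE)
  m <- mean(values)
  cv <- if (n >= 2L) 100 * stats::sd(values) / abs(m) else NA_real_
  list(mean = m, cv = cv, n = n)
}

#' Binarize a momentary pain report
#'
#' Mode `"momentary"` (default): pain iff the momentary 0-4 rating is >= 1,
#' matching models whose outcome is the probability of currently experiencing
#' knee pain. Mode `"any"` additionally counts between-call pain
#' ("reported pain since the last call but none right now") as pain.
#'
#' @param momentary_pain momentary rating 0-4 (NA when unanswered)
#' @param pain_since_last "yes"/"no" between-call pain flag
#' @param mode `"momentary"` or `"any"`
#' @return 0/1 (NA for unanswered reports)
#' @export
binarize_pain <- function(momentary_pain, pain_since_last = NULL,
                          mode = c("momentary", "any")) {
  mode <- match.arg(mode)
  out <- as.integer(momentary_pain >= 1)
  if (mode == "any" && !is.null(pain_since_last))
    out <- as.integer(out == 1L | pain_since_last == "yes")
  out
}

#' Spearman redundancy screen
#'
#' Spearman rank correlation (average ranks for ties, pairwise-complete)
#' across the supplied metric columns; metrics connected by |rho| >
#' `threshold` are clustered and each cluster collapsed to one
#' representative. When a cluster is ambiguous the representative preference
#' order keeps the 128 kHz resistance metric and the 40 kHz reactance metric
#' (columns whose names contain "r128" / "x40"), else the first column.
#'
#' @param metrics data.frame/matrix of numeric metric columns (>= 3 rows)
#' @param threshold |rho| above which metrics are considered redundant
#'   (default 0.9)
#' @return list with `rho` (correlation matrix), `clusters` (list of column
#'   name vectors), `retained` (character vector of kept columns)
#' @export
spearman_screen <- function(metrics, threshold = 0.9) {
  m <- as.matrix(metrics)
  if (nrow(m) < 3L) {
    warning("fewer than 3 complete rows; Spearman screen skipped")
    return(list(rho = NULL, clusters = NULL, retained = colnames(m)))
  }
  rho <- stats::cor(m, method = "spearman", use = "pairwise.complete.obs")
  p <- ncol(rho)
  # connected components of the |rho| > threshold graph
  comp <- seq_len(p)
  repeat {
    changed <- FALSE
    for (i in seq_len(p)) for (j in seq_len(p)) {
      if (i != j && !is.na(rho[i, j]) && abs(rho[i, j]) > threshold &&
          comp[j] != comp[i]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  nm <- colnames(rho)
  clusters <- split(nm, comp)
  names(clusters) <- NULL
  pick <- function(cl) {
    pref <- c(grep("r128", cl, value = TRUE), grep("x40", cl, value = TRUE))
    if (length(pref)) pref[1] else cl[1]
  }
  list(rho = rho, clusters = clusters,
       retained = vapply(clusters, pick, character(1)))
}

#' Reduce a whole study to the per-call-period metrics table
#'
#' Runs the QC decision tree and feature reduction for every participant:
#' session segmentation, self-test, sample range checks, window assignment,
#' period/day rules, per-length transform, and mean/CV reduction at the two
#' modelling frequencies (resistance at 128 kHz, reactance at 40 kHz). One
#' output row per kept (participant, day, call, configuration).
#'
#' @param study list with `participants` (incl. `L_longitudinal_m`,
#'   `L_transverse_m`, `group`), `reports` (ESM reports), and `logs` (named
#'   list of [device_log()] keyed by participant id)
#' @param config a [qc_config()]
#' @param mode pain binarization mode (see [binarize_pain()])
#' @return data.frame with columns `participant_id, group, day, call, config,
#'   plr128_mean, plr128_cv, plx40_mean, plx40_cv, pain`
#' @export
reduce_study <- function(study, config = qc_config(), mode = "momentary") {
  out <- list()
  for (pi in seq_len(nrow(study$participants))) {
    part <- study$participants[pi, ]
    pid <- part$participant_id
    log <- study$logs[[as.character(pid)]]
    if (is.null(log)) next
    reports <- study$reports[study$reports$participant_id == pid, , drop = FALSE]
    qp <- qc_pipeline(log, reports, config)
    kept <- qp$periods[qp$periods$kept, , drop = FALSE]
    if (nrow(kept) == 0L) next
    s <- log$samples
    clean <- qp$qc$samples$clean
    for (k in seq_len(nrow(kept))) {
      per <- kept[k, ]
      Lm <- if (per$config == "long") part$L_longitudinal_m else part$L_transverse_m
      # assignment indexes rows of the windowed periods (config-agnostic)
      widx <- match(paste(per$day, per$call_index),
                    paste(qp$win_periods$day, qp$win_periods$call_index))
      in_per <- !is.na(qp$assignment) & qp$assignment == widx &
        s$configuration == per$config & clean
      rvals <- s$resistance_ohm[in_per & s$frequency_khz == 128]
      xvals <- s$reactance_ohm[in_per & s$frequency_khz == 40]
      rr <- if (length(rvals)) reduce_period(per_length(rvals, Lm)) else
        list(mean = NA_real_, cv = NA_real_)
      xx <- if (length(xvals)) reduce_period(per_length(xvals, Lm)) else
        list(mean = NA_real_, cv = NA_real_)
      rep_row <- reports[reports$day == per$day &
                           reports$call_index == per$call_index, , drop = FALSE]
      pain <- binarize_pain(rep_row$momentary_pain[1],
                            rep_row$pain_since_last[1], mode)
      out[[length(out) + 1L]] <- data.frame(
        participant_id = pid, group = part$group, day = per$day,
        call = per$call_index, config = per$config,
        plr128_mean = rr$mean, plr128_cv = rr$cv,
        plx40_mean = xx$mean, plx40_cv = xx$cv, pain = pain,
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(participant_id = character(), group = integer(), day = integer(),
               call = integer(), config = character(), plr128_mean = numeric(),
               plr128_cv = numeric(), plx40_mean = numeric(),
               plx40_cv = numeric(), pain = integer())
  rownames(res) <- NULL
  res
}

#' Write / read the reduced-metrics CSV
#'
#' Layout: `participant_id,group,day,call,config,plr128_mean,plr128_cv,
#' plx40_mean,plx40_cv,pain`, one row per kept (participant, day, call,
#' configuration).
#'
#' @param reduced reduced-metrics data.frame
#' @param path CSV path
#' @return `path` / the data.frame
#' @export
write_reduced <- function(reduced, path) {
  utils::write.csv(reduced, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_reduced
#' @export
read_reduced <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
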