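# Synthetic study generator: participants, ESM schedules, raw multi-frequency
# impedance logs with injected artifacts, and momentary pain reports driven by
# a latent random-intercept logistic process with known ground truth. Every
# downstream stage (ingest, QC, reduction, modelling) is testable against the
# labels and parameters this module records.

#' Ground-truth generative parameters
#'
#' The pain process is a random-intercept logistic model on the per-length
#' 128 kHz transverse resistance (PLZ, ohm/m) and its CV (%):
#' logit P(pain) = gamma00 + gamma01 Group + gamma10 PLZ + gamma20 CV
#'   + Group (gamma11 PLZ + gamma21 CV) + u_j, u_j ~ N(0, sigma_u^2).
#'
#' Defaults place transverse per-length resistance near its free-living
#' operating range (roughly 370-500 ohm/m) and set sigma_u so the latent ICC
#' is about 0.59, the clustering level typical of momentary pain data.
#'
#' @param gamma00,gamma01,gamma10,gamma20,gamma11,gamma21 fixed effects
#'   (log-odds; slopes per ohm/m and per CV percent)
#' @param sigma_u random-intercept SD on the log-odds scale (>= 0)
#' @param plr128_mean per-configuration central per-length 128 kHz resistance
#'   (ohm/m), lognormal between participants with `plr_sdlog`
#' @param plx40_mean per-configuration central per-length 40 kHz reactance
#'   (ohm/m, negative)
#' @param plr_sdlog between-participant lognormal SD of baseline PLR
#' @param plx_sd between-participant SD of baseline PLX (ohm/m)
#' @param plz_within_sd call-to-call SD of the true per-period PLZ mean
#' @param cv_shape,cv_scale gamma parameters of the per-period CV (%)
#' @param drift_sd stationary SD of the slow AR(1) postural drift (ohm)
#' @param noise_sd per-sample measurement noise SD (ohm)
#' @param rating_weights categorical weights of momentary ratings 1-4 given a
#'   pain event (low ratings predominate)
#' @param between_call_pain_prob probability of a between-call pain flag
#' @return a `ground_truth` list
#' @export
ground_truth <- function(gamma00 = -7.0, gamma01 = 0.5, gamma10 = 0.007,
                         gamma20 = -0.05, gamma11 = 0.007, gamma21 = 0.05,
                         sigma_u = 2.16,
                         plr128_mean = c(long = 450, trans = 430),
                         plx40_mean = c(long = -27, trans = -25),
                         plr_sdlog = 0.14, plx_sd = 3,
                         plz_within_sd = 25,
                         cv_shape = 4, cv_scale = 0.75,
                         drift_sd = 1.5, noise_sd = 0.5,
                         rating_weights = c(0.45, 0.30, 0.15, 0.10),
                         between_call_pain_prob = 0.08) {
  check_that(sigma_u >= 0, "sigma_u", "must be non-negative")
  check_that(all(plx40_mean < 0), "plx40_mean",
             "central reactance values must be negative")
  structure(as.list(environment()), class = "ground_truth")
}

#' Cohort / study design configuration
#'
#' Defaults mirror the emulated free-living protocol: 20 participants (half
#' with knee OA), 7 wear days, one multi-frequency sample every 2.5 minutes at
#' 8/18/40/80/128 kHz from both electrode configurations, 4 ESM calls per day
#' randomised within 3-hour blocks between 08:00 and 20:00, and a 94.2% call
#' response rate.
#'
#' @param n_participants cohort size
#' @param oa_fraction fraction with knee OA in `[0, 1]`
#' @param n_days wear days (default 7)
#' @param sample_interval minutes between sample epochs (default 2.5)
#' @param frequencies stimulus frequencies in kHz, ascending
#' @param calls_per_day ESM calls per day (default 4)
#' @param call_window clock-hour range of the call window (default 8-20)
#' @param response_rate probability a call is answered (default 0.942)
#' @param artifact_rate per-sample probability of an isolated artifact
#'   (split evenly between out-of-band resistance spikes and deep phase
#'   excursions)
#' @param disconnect_event_rate expected electrode-disconnect bursts per day
#' @param wear_start_hour clock hour the brace goes on each day
#' @param wear_hours hours of powered wear per day
#' @param start_date first wear date (timezone-naive)
#' @param true_params a [ground_truth()]
#' @param seed integer seed (NULL leaves the RNG stream alone)
#' @return a `cohort_config` list
#' @export
cohort_config <- function(n_participants = 20L, oa_fraction = 0.5,
                          n_days = 7L, sample_interval = 2.5,
                          frequencies = c(8, 18, 40, 80, 128),
                          calls_per_day = 4L, call_window = c(8, 20),
                          response_rate = 0.942,
                          artifact_rate = 0.02, disconnect_event_rate = 1,
                          wear_start_hour = 7.75, wear_hours = 12.5,
                          start_date = "2026-01-05",
                          true_params = ground_truth(), seed = NULL) {
  check_that(n_participants >= 0, "n_participants", "must be >= 0")
  check_that(oa_fraction >= 0 && oa_fraction <= 1, "oa_fraction",
             "must lie in [0,1]")
  check_that(response_rate > 0 && response_rate <= 1, "response_rate",
             "must lie in (0,1]")
  check_that(sample_interval > 0, "sample_interval", "must be positive")
  check_that(all(frequencies > 0) && !is.unsorted(frequencies, strictly = TRUE),
             "frequencies", "must be positive and sorted ascending")
  check_that(calls_per_day >= 1, "calls_per_day", "must be >= 1")
  check_that(call_window[2] > call_window[1], "call_window",
             "end must exceed start")
  structure(as.list(environment()), class = "cohort_config")
}

#' Generate the participant table
#'
#' Knee circumference and age are drawn from truncated normals matching the
#' emulated sample characteristics; exactly `round(n_participants *
#' oa_fraction)` participants get `group = 1` (OA). Electrode spacings derive
#' deterministically from circumference: `L_transverse = circumference x
#' 0.25` and `L_longitudinal = 0.10 m`; brace size is the circumference's
#' ordinal bin (1-7).
#'
#' @param config a [cohort_config()]
#' @return data.frame of participants
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    n <- as.integer(config$n_participants)
    if (n == 0L)
      return(data.frame(participant_id = character(), group = integer(),
                        age = numeric(), knee_circumference_cm = numeric(),
                        brace_size = integer(), L_longitudinal_m = numeric(),
                        L_transverse_m = numeric()))
    circ <- pmin(pmax(stats::rnorm(n, 41.2, 4.4), 33.0), 50.8)
    age <- pmin(pmax(stats::rnorm(n, 73.5, 8.26), 57), 89)
    n_oa <- round(n * config$oa_fraction)
    group <- integer(n)
    group[sample.int(n, n_oa)] <- 1L
    data.frame(
      participant_id = sprintf("P%02d", seq_len(n)),
      group = group,
      age = round(age, 1),
      knee_circumference_cm = round(circ, 1),
      brace_size = as.integer(cut(circ, breaks = seq(33, 50.8, length.out = 8),
                                  include.lowest = TRUE, labels = FALSE)),
      L_longitudinal_m = 0.10,
      L_transverse_m = round(circ, 1) / 100 * 0.25,
      stringsAsFactors = FALSE)
  })
}

#' Generate one participant's randomised ESM call schedule
#'
#' The call window is divided into `calls_per_day` equal blocks (3 h each by
#' default) and one call time is drawn uniformly inside each block; each call
#' is independently answered with probability `response_rate`.
#'
#' @param participant one row of the participant table
#' @param config a [cohort_config()]
#' @param seed optional seed for this participant's schedule
#' @return data.frame: `participant_id`, `day`, `call_index`, `timestamp`,
#'   `answered`
#' @export
generate_esm_schedule <- function(participant, config = cohort_config(),
                                  seed = NULL) {
  with_seed(seed, {
    window_h <- config$call_window[2] - config$call_window[1]
    block_h <- window_h / config$calls_per_day
    base <- as.POSIXct(paste(config$start_date, "00:00:00"), tz = "UTC")
    rows <- list()
    for (d in seq_len(config$n_days)) {
      offs <- (config$call_window[1] +
                 (seq_len(config$calls_per_day) - 1L) * block_h +
                 stats::runif(config$calls_per_day) * block_h) * 3600
      ts <- base + (d - 1L) * 86400 + round(offs)
      rows[[d]] <- data.frame(
        participant_id = participant$participant_id, day = d,
        call_index = seq_len(config$calls_per_day),
        timestamp = ts,
        answered = stats::runif(config$calls_per_day) < config$response_rate,
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
}

# frequency scaling of the clean baseline relative to the modelling
# frequencies (resistance falls and |reactance| shifts with frequency)
.r_freq_scale <- c(`8` = 1.25, `18` = 1.18, `40` = 1.10, `80` = 1.04, `128` = 1)
.x_freq_scale <- c(`8` = 0.60, `18` = 0.85, `40` = 1.00, `80` = 0.92, `128` = 0.80)

# Participant-level baseline per-length values (ohm/m), reproducible from the
# participant's own sub-seed.
participant_baseline <- function(participant, truth, seed = NULL) {
  with_seed(seed, {
    plr <- stats::rlnorm(2, log(truth$plr128_mean) - truth$plr_sdlog^2 / 2,
                         truth$plr_sdlog)
    plx <- pmin(stats::rnorm(2, truth$plx40_mean, truth$plx_sd), -5)
    list(plr128 = stats::setNames(plr, names(truth$plr128_mean)),
         plx40 = stats::setNames(plx, names(truth$plx40_mean)))
  })
}

#' Generate one participant's raw device log with injected artifacts
#'
#' Per wear day: a contiguous powered interval sampled every
#' `sample_interval` minutes at all frequencies and both configurations;
#' battery voltage discharges linearly from 4.2 V to 3.5 V within the
#' session; one on-board self-test record per session per frequency (healthy
#' devices: measured within +/-5% of the 100-ohm nominal). Clean samples are
#' baseline + slow AR(1) drift + noise, clamped inside the physiologic
#' acceptance bands. Three artifact kinds are injected and labelled in the
#' `artifact_truth` column: electrode-disconnect bursts (resistance and phase
#' driven far out of band), deep phase excursions below -50 degrees, and
#' isolated out-of-band resistance spikes.
#'
#' @param participant one row of the participant table
#' @param schedule that participant's ESM schedule (used only to align dates)
#' @param config a [cohort_config()]
#' @param seed optional seed
#' @return a [device_log()] whose samples carry an `artifact_truth` label
#' @export
generate_device_log <- function(participant, schedule,
                                config = cohort_config(), seed = NULL) {
  truth <- config$true_params
  with_seed(seed, {
    base_pl <- participant_baseline(participant, truth)
    Lv <- c(long = participant$L_longitudinal_m,
            trans = participant$L_transverse_m)
    base_date <- as.POSIXct(paste(config$start_date, "00:00:00"), tz = "UTC")
    n_ep <- as.integer(floor(config$wear_hours * 60 / config$sample_interval))
    rho <- 0.99
    all_rows <- list()
    selftests <- list()
    for (d in seq_len(config$n_days)) {
      t0 <- base_date + (d - 1L) * 86400 +
        round(config$wear_start_hour * 3600 + stats::runif(1, 0, 1200))
      ts <- t0 + (seq_len(n_ep) - 1L) * round(config$sample_interval * 60)
      batt <- seq(4.2, 3.5, length.out = n_ep)
      for (cfg in c("long", "trans")) {
        R128 <- base_pl$plr128[[cfg]] * Lv[[cfg]]
        X40 <- base_pl$plx40[[cfg]] * Lv[[cfg]]
        # shared slow drift across frequencies (stationary AR(1))
        e <- numeric(n_ep)
        e[1] <- stats::rnorm(1, 0, truth$drift_sd)
        innov <- stats::rnorm(n_ep - 1L, 0, truth$drift_sd * sqrt(1 - rho^2))
        for (t in seq_len(n_ep - 1L)) e[t + 1L] <- rho * e[t] + innov[t]
        for (f in config$frequencies) {
          fs <- .r_freq_scale[as.character(f)]
          xs <- .x_freq_scale[as.character(f)]
          if (is.na(fs)) { fs <- 1; xs <- 1 }
          R <- (R128 + e) * fs + stats::rnorm(n_ep, 0, truth$noise_sd)
          X <- X40 * xs + 0.1 * e + stats::rnorm(n_ep, 0, truth$noise_sd / 3)
          # clamp clean values inside the acceptance bands
          R <- pmin(pmax(R, 5), 205)
          X <- pmin(X, -0.005 * R)
          X <- pmax(X, tan(-49 * pi / 180) * R)
          lab <- rep("clean", n_ep)
          # isolated artifacts
          u <- stats::runif(n_ep)
          spike <- u < config$artifact_rate / 2
          phasex <- !spike & u < config$artifact_rate
          if (any(spike)) {
            R[spike] <- stats::runif(sum(spike), 215, 400)
            X[spike] <- -0.05 * R[spike]
            lab[spike] <- "spike"
          }
          if (any(phasex)) {
            ang <- stats::runif(sum(phasex), -85, -55) * pi / 180
            X[phasex] <- R[phasex] * tan(ang)
            lab[phasex] <- "phase"
          }
          all_rows[[length(all_rows) + 1L]] <- data.frame(
            timestamp = ts, configuration = cfg, frequency_khz = f,
            resistance_ohm = R, reactance_ohm = X, battery_v = batt,
            artifact_truth = lab, day = d, stringsAsFactors = FALSE)
        }
      }
      for (f in config$frequencies)
        selftests[[length(selftests) + 1L]] <- data.frame(
          session_index = d, frequency_khz = f, nominal_ohm = 100,
          measured_ohm = 100 * (1 + stats::runif(1, -0.05, 0.05)))
    }
    samples <- do.call(rbind, all_rows)
    # disconnect bursts: per day, per event, one configuration, all freqs
    for (d in seq_len(config$n_days)) {
      n_ev <- stats::rpois(1, config$disconnect_event_rate)
      if (n_ev == 0) next
      for (ev in seq_len(n_ev)) {
        cfg <- sample(c("long", "trans"), 1)
        start <- sample.int(n_ep, 1)
        len <- 1L + stats::rgeom(1, 1 / 5)
        hit_ep <- start:min(start + len - 1L, n_ep)
        day_cfg <- which(samples$day == d & samples$configuration == cfg)
        ep_index <- match(samples$timestamp[day_cfg],
                          sort(unique(samples$timestamp[day_cfg])))
        hit <- day_cfg[ep_index %in% hit_ep]
        samples$resistance_ohm[hit] <- stats::runif(length(hit), 300, 2000)
        samples$reactance_ohm[hit] <- stats::runif(length(hit), 1, 50)
        samples$artifact_truth[hit] <- "disconnect"
      }
    }
    samples$day <- NULL
    log <- device_log(participant$participant_id, samples,
                      do.call(rbind, selftests),
                      reported_wear_days = config$n_days)
    log
  })
}

#' Ground-truth per-call reduced metrics (fast parametric path)
#'
#' Draws the true per-period PLZ mean and CV for each answered call directly
#' from their generative distributions, bypassing raw-log simulation. This is
#' the path used for large model-validation cohorts where simulating every
#' 2.5-minute sample would be wasteful; `simulate_study()` instead derives
#' these from the generated clean samples.
#'
#' @param participant one row of the participant table
#' @param schedule the participant's ESM schedule
#' @param truth a [ground_truth()]
#' @param configuration electrode configuration of the modelled metric
#' @param seed optional seed
#' @return data.frame: `day`, `call_index`, `plz`, `cv`
#' @export
generate_reduced_truth <- function(participant, schedule, truth,
                                   configuration = "trans", seed = NULL) {
  with_seed(seed, {
    ans <- schedule[schedule$answered, , drop = FALSE]
    base <- participant_baseline(participant, truth)$plr128[[configuration]]
    data.frame(day = ans$day, call_index = ans$call_index,
               plz = base + stats::rnorm(nrow(ans), 0, truth$plz_within_sd),
               cv = stats::rgamma(nrow(ans), truth$cv_shape,
                                  scale = truth$cv_scale))
  })
}

#' Generate one participant's ESM pain reports from the latent pain process
#'
#' A participant-level random intercept u_j ~ N(0, sigma_u^2) is drawn once;
#' each answered call's pain indicator is Bernoulli(logistic(linear
#' predictor)) with the linear predictor built from the ground-truth
#' coefficients and that call's true reduced metric. The momentary 0-4 rating
#' is 0 under no pain and categorical over 1-4 under pain; the between-call
#' pain flag has its own probability.
#'
#' @param participant one row of the participant table
#' @param schedule the participant's ESM schedule
#' @param reduced_truth per-answered-call true metrics (see
#'   [generate_reduced_truth()])
#' @param truth a [ground_truth()]
#' @param seed optional seed
#' @return data.frame of ESM reports: `participant_id`, `day`, `call_index`,
#'   `timestamp`, `answered`, `momentary_pain`, `pain_since_last`; the drawn
#'   random intercept is attached as attribute `u0`
#' @export
generate_pain_reports <- function(participant, schedule, reduced_truth, truth,
                                  seed = NULL) {
  with_seed(seed, {
    u0 <- stats::rnorm(1, 0, truth$sigma_u)
    rep <- schedule
    rep$momentary_pain <- NA_integer_
    rep$pain_since_last <- NA_character_
    grp <- participant$group
    idx <- which(rep$answered)
    m <- match(paste(rep$day[idx], rep$call_index[idx]),
               paste(reduced_truth$day, reduced_truth$call_index))
    # answered calls without a ground-truth metric revert to unanswered
    rep$answered[idx[is.na(m)]] <- FALSE
    idx <- idx[!is.na(m)]
    m <- m[!is.na(m)]
    if (length(idx)) {
      plz <- reduced_truth$plz[m]
      cv <- reduced_truth$cv[m]
      eta <- truth$gamma00 + truth$gamma01 * grp + truth$gamma10 * plz +
        truth$gamma20 * cv + u0 +
        grp * (truth$gamma11 * plz + truth$gamma21 * cv)
      pain <- stats::rbinom(length(idx), 1, stats::plogis(eta))
      rating <- integer(length(idx))
      if (any(pain == 1L))
        rating[pain == 1L] <- sample(1:4, sum(pain), replace = TRUE,
                                     prob = truth$rating_weights)
      rep$momentary_pain[idx] <- rating
      rep$pain_since_last[idx] <-
        ifelse(stats::runif(length(idx)) < truth$between_call_pain_prob,
               "yes", "no")
    }
    attr(rep, "u0") <- u0
    rep
  })
}

#' Simulate a complete synthetic study
#'
#' End-to-end generation: cohort, per-participant ESM schedules, raw device
#' logs with artifact labels, ground-truth per-call reduced metrics computed
#' from the *clean* generated samples (so the pain process is genuinely
#' coupled to the observable impedance), and pain reports. Deterministic:
#' the same `config` (including `seed`) reproduces the study byte for byte.
#'
#' @param config a [cohort_config()]
#' @return list with `participants`, `reports`, `logs` (named list of
#'   [device_log()]), `reduced_truth` (per participant), `truth`, `config`
#' @export
simulate_study <- function(config = cohort_config(seed = 1L)) {
  participants <- generate_cohort(config)
  truth <- config$true_params
  logs <- list()
  reports <- list()
  reduced_truth <- list()
  base_seed <- if (is.null(config$seed)) 0L else config$seed
  for (i in seq_len(nrow(participants))) {
    part <- participants[i, ]
    sched <- generate_esm_schedule(part, config, seed = base_seed + 10000L + i)
    log <- generate_device_log(part, sched, config,
                               seed = base_seed + 20000L + i)
    # true reduced metric per answered call, from clean samples only
    s <- log$samples
    clean <- s$artifact_truth == "clean" & s$configuration == "trans" &
      s$frequency_khz == 128
    win <- window_samples(s[clean, , drop = FALSE], sched)
    rt <- do.call(rbind, lapply(seq_len(nrow(win$periods)), function(k) {
      vals <- s$resistance_ohm[clean][which(win$assignment == k)]
      if (length(vals) >= 2L) {
        red <- reduce_period(per_length(vals, part$L_transverse_m))
        data.frame(day = win$periods$day[k],
                   call_index = win$periods$call_index[k],
                   plz = red$mean, cv = red$cv)
      } else NULL
    }))
    if (is.null(rt)) rt <- data.frame(day = integer(), call_index = integer(),
                                      plz = numeric(), cv = numeric())
    rep <- generate_pain_reports(part, sched, rt, truth,
                                 seed = base_seed + 30000L + i)
    logs[[part$participant_id]] <- log
    reports[[i]] <- rep
    reduced_truth[[part$participant_id]] <- rt
  }
  list(participants = participants,
       reports = if (length(reports)) do.call(rbind, reports) else NULL,
       logs = logs, reduced_truth = reduced_truth, truth = truth,
       config = config)
}

#' Simulate a reduced-metrics cohort directly (for model validation)
#'
#' Fast parametric path: skips raw-log generation and QC, drawing the true
#' per-call reduced metrics and pain outcomes directly. Emits transverse-
#' configuration rows in the standard reduced-table layout, ready for
#' [fit_model()]. Used for parameter-recovery and power simulations where
#' hundreds of participants are needed.
#'
#' @param n_participants cohort size
#' @param truth a [ground_truth()]
#' @param n_days,calls_per_day,response_rate schedule parameters
#' @param seed integer seed
#' @return list with `reduced` (reduced-metrics data.frame) and `truth`
#' @export
simulate_reduced_cohort <- function(n_participants = 200L,
                                    truth = ground_truth(),
                                    n_days = 7L, calls_per_day = 4L,
                                    response_rate = 1.0, seed = NULL) {
  config <- cohort_config(n_participants = n_participants, n_days = n_days,
                          calls_per_day = calls_per_day,
                          response_rate = response_rate,
                          true_params = truth, seed = seed)
  participants <- generate_cohort(config)
  base_seed <- if (is.null(seed)) 0L else seed
  rows <- vector("list", n_participants)
  for (i in seq_len(nrow(participants))) {
    part <- participants[i, ]
    sched <- generate_esm_schedule(part, config, seed = base_seed + 10000L + i)
    rt <- generate_reduced_truth(part, sched, truth,
                                 seed = base_seed + 20000L + i)
    rep <- generate_pain_reports(part, sched, rt, truth,
                                 seed = base_seed + 30000L + i)
    ans <- rep[rep$answered, , drop = FALSE]
    rt <- rt[match(paste(ans$day, ans$call_index),
                   paste(rt$day, rt$call_index)), , drop = FALSE]
    rows[[i]] <- data.frame(
      participant_id = part$participant_id, group = part$group,
      day = ans$day, call = ans$call_index, config = "trans",
      plr128_mean = rt$plz, plr128_cv = rt$cv,
      plx40_mean = NA_real_, plx40_cv = NA_real_,
      pain = binarize_pain(ans$momentary_pain),
      stringsAsFactors = FALSE)
  }
  list(reduced = do.call(rbind, rows), truth = truth)
}

#' Write a simulated study to disk
#'
#' Emits the participants CSV, the ESM-report CSV, one device-log CSV and one
#' self-test CSV per participant (canonical dialect), and a ground-truth JSON
#' sidecar with all generative parameters and per-sample artifact labels.
#'
#' @param study output of [simulate_study()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(study$participants, file.path(dir, "participants.csv"),
                   row.names = FALSE, quote = FALSE)
  rep <- study$reports
  rep$timestamp <- format_ts(rep$timestamp)
  names(rep)[names(rep) == "momentary_pain"] <- "momentary_pain_0_4"
  names(rep)[names(rep) == "pain_since_last"] <- "pain_since_last_yn"
  utils::write.csv(rep, file.path(dir, "esm_reports.csv"),
                   row.names = FALSE, quote = FALSE)
  labels <- list()
  for (pid in names(study$logs)) {
    log <- study$logs[[pid]]
    write_device_log(log, file.path(dir, paste0("device_", pid, ".csv")),
                     file.path(dir, paste0("selftest_", pid, ".csv")))
    labels[[pid]] <- log$samples$artifact_truth
  }
  sidecar <- list(truth = unclass(study$truth),
                  seed = study$config$seed,
                  artifact_labels = labels)
  jsonlite::write_json(sidecar, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
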