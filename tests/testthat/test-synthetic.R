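test_that("generate_cohort hits the exact OA split, empty case, determinism", {
  cfg <- cohort_config(n_participants = 20, oa_fraction = 0.5, seed = 3)
  coh <- generate_cohort(cfg)
  expect_equal(sum(coh$group == 1), 10)
  expect_equal(sum(coh$group == 0), 10)
  expect_true(all(coh$L_longitudinal_m > 0) && all(coh$L_transverse_m > 0))
  # L derives deterministically from circumference
  expect_equal(coh$L_transverse_m, coh$knee_circumference_cm / 100 * 0.25)

  expect_equal(nrow(generate_cohort(cohort_config(n_participants = 0))), 0)
  expect_identical(generate_cohort(cfg), coh)

  # odd splits still round
  c21 <- generate_cohort(cohort_config(n_participants = 21, oa_fraction = 0.5,
                                       seed = 1))
  expect_equal(sum(c21$group), round(21 * 0.5))
})

test_that("cohort_config validates fields by name", {
  expect_error(cohort_config(oa_fraction = 1.5), "oa_fraction")
  expect_error(cohort_config(response_rate = 0), "response_rate")
  expect_error(cohort_config(sample_interval = -1), "sample_interval")
  expect_error(cohort_config(frequencies = c(40, 8)), "frequencies")
})

test_that("ESM schedule: blocks, counts, response rate", {
  cfg <- cohort_config(n_participants = 1, response_rate = 1, seed = 5)
  part <- generate_cohort(cfg)[1, ]
  sch <- generate_esm_schedule(part, cfg, seed = 9)
  expect_equal(sum(sch$answered), 28) # 7 days x 4 calls, all answered
  # one call per 3-h block, strictly increasing within a day
  for (d in unique(sch$day)) {
    h <- as.numeric(format(sch$timestamp[sch$day == d], "%H")) +
      as.numeric(format(sch$timestamp[sch$day == d], "%M")) / 60
    expect_true(all(diff(sch$timestamp[sch$day == d]) > 0))
    expect_true(all(h >= 8 & h < 20))
    expect_equal(floor((h - 8) / 3), 0:3)
  }

  cfg0 <- cohort_config(n_participants = 1, response_rate = 1e-12, seed = 5)
  sch0 <- generate_esm_schedule(part, cfg0, seed = 9)
  expect_equal(sum(sch0$answered), 0)

  # answered-call total across 20 participants is binomial around 527
  cfg94 <- cohort_config(response_rate = 0.942, seed = 2)
  coh <- generate_cohort(cfg94)
  tot <- sum(vapply(seq_len(20), function(i)
    sum(generate_esm_schedule(coh[i, ], cfg94, seed = 100 + i)$answered),
    numeric(1)))
  expect_lt(abs(tot - 560 * 0.942), 3 * sqrt(560 * 0.942 * 0.058))
})

test_that("device logs: epochs per day, battery sessions, clean-band guarantee", {
  cfg <- cohort_config(n_participants = 1, n_days = 1, wear_hours = 20,
                       artifact_rate = 0, disconnect_event_rate = 0, seed = 4)
  part <- generate_cohort(cfg)[1, ]
  sch <- generate_esm_schedule(part, cfg, seed = 1)
  log <- generate_device_log(part, sch, cfg, seed = 2)
  expect_equal(length(unique(log$samples$timestamp)), 480) # 20 h x 2.5 min

  # with no artifacts every sample passes the range checks
  s <- log$samples
  expect_true(all(s$artifact_truth == "clean"))
  expect_true(all(s$resistance_ohm > 0 & s$resistance_ohm < 212))
  expect_true(all(s$phase_deg > -50 & s$phase_deg < 0))
  expect_true(all(s$reactance_ohm < 0))

  # battery voltage non-increasing within the session
  ep <- order(unique(s$timestamp))
  bv <- s$battery_v[match(sort(unique(s$timestamp)), s$timestamp)]
  expect_true(all(diff(bv) <= 0))

  # 7 wear days -> 7 distinguishable discharge sessions
  cfg7 <- cohort_config(n_participants = 1, n_days = 7, seed = 4)
  log7 <- generate_device_log(part, generate_esm_schedule(part, cfg7, seed = 1),
                              cfg7, seed = 2)
  expect_equal(nrow(segment_sessions(log7)), 7)
  expect_equal(nrow(log7$selftests), 7 * 5)
})

test_that("injected artifacts always violate a range check (label soundness)", {
  cfg <- cohort_config(n_participants = 1, n_days = 3, artifact_rate = 0.05,
                       disconnect_event_rate = 2, seed = 8)
  part <- generate_cohort(cfg)[1, ]
  log <- generate_device_log(part, generate_esm_schedule(part, cfg, seed = 1),
                             cfg, seed = 2)
  s <- log$samples
  art <- s$artifact_truth != "clean"
  expect_gt(sum(art), 0)
  violates <- !(s$resistance_ohm > 0 & s$resistance_ohm < 212 &
                  s$phase_deg > -50 & s$phase_deg < 0)
  expect_true(all(violates[art]))
  expect_true(!any(violates[!art]))
})

test_that("pain generation: null process, consistency, prevalence calibration", {
  truth0 <- ground_truth(gamma00 = 0, gamma01 = 0, gamma10 = 0, gamma20 = 0,
                         gamma11 = 0, gamma21 = 0, sigma_u = 0)
  cfg <- cohort_config(n_participants = 40, response_rate = 1,
                       true_params = truth0, seed = 21)
  coh <- generate_cohort(cfg)
  pains <- unlist(lapply(seq_len(nrow(coh)), function(i) {
    sch <- generate_esm_schedule(coh[i, ], cfg, seed = 300 + i)
    rt <- generate_reduced_truth(coh[i, ], sch, truth0, seed = 400 + i)
    rep <- generate_pain_reports(coh[i, ], sch, rt, truth0, seed = 500 + i)
    m <- rep$momentary_pain[rep$answered]
    # no-pain indicator must give a 0 rating
    expect_true(all(m %in% 0:4))
    m
  }))
  prev <- mean(pains >= 1) # logistic(0) = 0.5
  expect_lt(abs(prev - 0.5), 3 * sqrt(0.25 / length(pains)))

  # calibration against the linear predictor with known intercepts
  truth <- ground_truth()
  cfgc <- cohort_config(n_participants = 400, response_rate = 1,
                        true_params = truth, seed = 22)
  cohc <- generate_cohort(cfgc)
  emp <- 0; expected <- 0; n_calls <- 0; var_sum <- 0
  for (i in seq_len(nrow(cohc))) {
    sch <- generate_esm_schedule(cohc[i, ], cfgc, seed = 1000 + i)
    rt <- generate_reduced_truth(cohc[i, ], sch, truth, seed = 2000 + i)
    rep <- generate_pain_reports(cohc[i, ], sch, rt, truth, seed = 3000 + i)
    u0 <- attr(rep, "u0")
    g <- cohc$group[i]
    eta <- truth$gamma00 + truth$gamma01 * g + truth$gamma10 * rt$plz +
      truth$gamma20 * rt$cv + u0 + g * (truth$gamma11 * rt$plz +
                                          truth$gamma21 * rt$cv)
    p <- plogis(eta)
    emp <- emp + sum(rep$momentary_pain[rep$answered] >= 1)
    expected <- expected + sum(p)
    var_sum <- var_sum + sum(p * (1 - p))
    n_calls <- n_calls + sum(rep$answered)
  }
  expect_gte(n_calls, 1e4)
  mc_se <- sqrt(var_sum) / n_calls
  expect_lt(abs(emp / n_calls - expected / n_calls), 3 * mc_se)
})

test_that("simulate_study is deterministic and internally consistent", {
  cfg <- cohort_config(n_participants = 3, n_days = 2, seed = 99)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$participants, s2$participants)
  expect_identical(s1$reports, s2$reports)
  expect_identical(lapply(s1$logs, `[[`, "samples"),
                   lapply(s2$logs, `[[`, "samples"))
  # unanswered calls never carry a momentary rating
  expect_true(all(is.na(s1$reports$momentary_pain[!s1$reports$answered])))
  expect_true(all(!is.na(s1$reports$momentary_pain[s1$reports$answered])))
})

test_that("write_study emits the documented files and a loadable sidecar", {
  dir <- withr::local_tempdir()
  cfg <- cohort_config(n_participants = 2, n_days = 2, seed = 13)
  study <- simulate_study(cfg)
  write_study(study, dir)
  expect_true(file.exists(file.path(dir, "participants.csv")))
  expect_true(file.exists(file.path(dir, "esm_reports.csv")))
  expect_true(file.exists(file.path(dir, "device_P01.csv")))
  expect_true(file.exists(file.path(dir, "selftest_P02.csv")))
  side <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_equal(side$truth$sigma_u, study$truth$sigma_u)
  expect_equal(length(side$artifact_labels$P01),
               nrow(study$logs$P01$samples))
})
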