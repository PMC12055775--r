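test_that("constant gaze yields no events; tiny spikes are rejected", {
  rec <- make_recording(numeric(600))
  expect_equal(nrow(detect_saccades(rec)), 0L)
  x <- numeric(600); x[300] <- 0.5           # 1-sample 0.5 deg spike
  expect_equal(nrow(detect_saccades(make_recording(x))), 0L)
})

test_that("a noiseless minimum-jerk saccade is recovered accurately", {
  x <- make_gaze(list(list(onset = 0.5, amp = 10, vp = 400)), n = 240)
  ev <- detect_saccades(make_recording(x))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$amplitude_deg, 10, tolerance = 0.2)
  expect_lt(abs(ev$peak_velocity_dps / 400 - 1), 0.05)
  expect_identical(ev$direction, "right")
  expect_gt(ev$peak_velocity_dps, ev$mean_velocity_dps)
})

test_that("detection requires adequate sampling rate", {
  x <- make_gaze(list(list(onset = 0.5, amp = 10, vp = 300)), n = 100, fs = 50)
  rec <- gaze_recording("s", "PD", "pro_saccade", 50, (0:99) / 50, x,
                        pupil_left_mm = rep(3, 100), pupil_right_mm = rep(3, 100))
  expect_error(detect_saccades(rec), "60 Hz")
})

test_that("detector matches the brute-force threshold-scan oracle", {
  set.seed(31)
  n_trials <- 100
  mismatches <- 0
  for (i in seq_len(n_trials)) {
    amp <- sample(c(-1, 1), 1) * runif(1, 3, 12)
    vp <- runif(1, 30, 55) * abs(amp)   # main-sequence-consistent speeds
    onset <- runif(1, 0.3, 1.2)
    x <- make_gaze(list(list(onset = onset, amp = amp, vp = vp)), n = 300)
    rec <- make_recording(x)
    ev <- detect_saccades(rec)
    orc <- oracle_detect(x, FS)
    expect_equal(nrow(ev), length(orc))
    if (nrow(ev) == 1 && length(orc) == 1) {
      onset_idx <- round(ev$onset_s * FS) + 1
      if (abs(onset_idx - orc[[1]]["onset_idx"]) > 1) mismatches <- mismatches + 1
      # kinematic recovery against generator truth
      expect_lt(abs(ev$amplitude_deg - amp), max(0.2, 0.05 * abs(amp)))
      expect_lt(abs(ev$peak_velocity_dps / vp - 1), 0.05)
    }
  }
  expect_equal(mismatches, 0)
})

test_that("pro trial scoring follows the constructed example", {
  # stimulus right at 1.0 s, saccade onset 1.27 s landing ~9.8 deg
  x <- make_gaze(list(list(onset = 1.27, amp = 9.8, vp = 400)), n = 600)
  clean <- preprocess_recording(make_recording(x),
                                build_schedule("pro_saccade", 10, seed = 1,
                                               n_per_side = 1))
  sch <- clean$schedule
  sch$side <- "right"
  sc <- score_trial(sch[1, ], detect_saccades(clean), clean, "pro_saccade")
  expect_true(sc$correct)
  expect_equal(sc$first_saccade_latency_ms, 270, tolerance = 10)
  expect_gt(sc$time_to_complete_ms, sc$first_saccade_latency_ms)
})

test_that("anti trial scoring detects errors, corrections and their timing", {
  # stimulus right at 1.0 s: error saccade right at 1.25 s, corrective left
  # saccade starting 230 ms after the error saccade ends
  err <- list(onset = 1.25, amp = 9.5, vp = 450)
  err_end <- 1.25 + 1.875 * 9.5 / 450
  corr <- list(onset = err_end + 0.23, amp = -19, vp = 500)
  x <- make_gaze(list(err, corr), n = 600)
  clean <- preprocess_recording(make_recording(x, task = "anti_saccade"),
                                build_schedule("anti_saccade", 10, seed = 1,
                                               n_per_side = 1))
  sch <- clean$schedule; sch$side <- "right"
  sc <- score_trial(sch[1, ], detect_saccades(clean), clean, "anti_saccade")
  expect_true(sc$direction_error)
  expect_true(sc$corrected)
  expect_false(sc$correct)
  expect_equal(sc$correction_time_ms, 230, tolerance = 20)

  # same error with no corrective follow-up
  x2 <- make_gaze(list(err), n = 600)
  clean2 <- preprocess_recording(make_recording(x2, task = "anti_saccade"),
                                 build_schedule("anti_saccade", 10, seed = 1,
                                                n_per_side = 1))
  sc2 <- score_trial(sch[1, ], detect_saccades(clean2), clean2, "anti_saccade")
  expect_true(sc2$direction_error)
  expect_false(sc2$corrected)
  expect_true(is.na(sc2$correction_time_ms))
})

test_that("no saccade in the window marks the trial as a non-response", {
  clean <- preprocess_recording(make_recording(numeric(600)),
                                build_schedule("pro_saccade", 10, seed = 1,
                                               n_per_side = 1))
  sc <- score_trial(clean$schedule[1, ], detect_saccades(clean), clean,
                    "pro_saccade")
  expect_false(sc$responded)
  expect_false(sc$correct)
  expect_true(is.na(sc$first_saccade_latency_ms))
  expect_true(sc$valid_trial)
})

test_that("summary arithmetic follows the definitions", {
  mk_scores <- function(n, correct, task = "pro_saccade",
                        err = logical(n), corr = logical(n)) {
    data.frame(trial_index = seq_len(n) - 1, task = task, valid_trial = TRUE,
               responded = TRUE, first_saccade_latency_ms = 250,
               correct = correct,
               direction_error = if (task == "anti_saccade") err else NA,
               corrected = if (task == "anti_saccade") corr else NA,
               correction_time_ms = ifelse(corr, 200, NA_real_),
               time_to_complete_ms = 400, peak_velocity_dps = 450,
               mean_velocity_dps = 220)
  }
  pro <- mk_scores(40, rep(c(TRUE, FALSE), c(34, 6)))
  anti <- mk_scores(40, rep(FALSE, 40), task = "anti_saccade",
                    err = rep(c(TRUE, FALSE), c(10, 30)),
                    corr = rep(c(TRUE, FALSE, FALSE), c(3, 7, 30)))
  s <- summarize_subject(pro, anti, "s1", "PD")
  expect_equal(s$pro_accuracy_pct, 85)            # 34/40
  expect_equal(s$anti_correction_rate_pct, 30)    # 3/10
  expect_equal(s$anti_correction_time_ms, 200)
  expect_equal(s$pro_ttc_min_ms, s$pro_ttc_avg_ms)
  expect_error(summarize_subject(pro[pro$correct & FALSE, ], anti), "valid")
})

test_that("scored accuracy tracks the generating probability", {
  prof <- quiet_profile(pro_correct_prob = 0.9)
  cfg <- cohort_config(n_pd = 1, n_control = 1, pd_profile = prof,
                       control_profile = prof, seed = 2)
  correct <- 0; valid <- 0
  for (i in 1:8) {
    s <- simulate_subject("PD", cfg, 300 + i)
    clean <- preprocess_recording(s$recordings$pro_saccade,
                                  s$schedules$pro_saccade)
    sc <- score_trials(clean)
    sc <- sc[sc$valid_trial, ]
    correct <- correct + sum(sc$correct); valid <- valid + nrow(sc)
  }
  ci <- binom.test(correct, valid, p = 0.9)$conf.int
  expect_true(ci[1] <= 0.9 && 0.9 <= ci[2])
})

test_that("accuracy and correction scoring ignore pupil-channel noise", {
  cfg <- small_config(n_pd = 1, n_control = 1, seed = 23)
  s <- simulate_subject("PD", cfg, 88)
  rec <- s$recordings$anti_saccade
  sch <- s$schedules$anti_saccade
  base_sc <- score_trials(preprocess_recording(rec, sch))
  noisy <- rec
  set.seed(1)
  noisy$pupil_left_mm <- pmax(noisy$pupil_left_mm +
                                rnorm(length(noisy$t), 0, 0.02), 0.01)
  noisy_sc <- score_trials(preprocess_recording(noisy, sch))
  expect_identical(base_sc$correct, noisy_sc$correct)
  expect_identical(base_sc$corrected, noisy_sc$corrected)
})
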