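test_that("minimum-jerk waveform has closed-form duration and displacement", {
  w <- synth_saccade_waveform(10, 400, 0, 120)
  expect_equal(w$duration_s, 1.875 * 10 / 400)        # 46.875 ms
  expect_equal(w$x[1], 0)
  expect_equal(w$x[length(w$x)], 10)
  expect_true(all(diff(w$x) >= 0))                    # monotone displacement
  # mirror symmetry for leftward saccades
  wl <- synth_saccade_waveform(-10, 400, 0, 120)
  expect_equal(wl$x, -w$x)
})

test_that("waveform peak speed matches the request (dense-grid oracle)", {
  for (vp in c(200, 400, 550)) {
    w <- synth_saccade_waveform(10, vp, 0, 2000)      # dense grid
    peak <- max(abs(diff(w$x))) * 2000
    expect_lt(abs(peak / vp - 1), 0.05)
  }
})

test_that("waveform rejects degenerate parameters", {
  expect_error(synth_saccade_waveform(0, 400, 0, 120), "non-zero")
  expect_error(synth_saccade_waveform(10, -5, 0, 120), "> 0")
  # duration below 2 samples
  expect_error(synth_saccade_waveform(1, 2000, 0, 120), "2 samples")
})

test_that("pupil signal reduces to the constant baseline in the quiet limit", {
  p <- quiet_profile(constriction_amp_mm = c(0, 0),
                     band_osc_amp_mm = data.frame(freq_hz = numeric(0),
                                                  amp_mean = numeric(0),
                                                  amp_sd = numeric(0)))
  sch <- build_schedule("pro_saccade", 10, seed = 1)
  sig <- synth_pupil_signal(p, sch, 120)
  expect_equal(sig$left, rep(p$pupil_baseline_mm[1], length(sig$t)))
  expect_equal(sig$right, sig$left)
})

test_that("a single band oscillation appears at its amplitude in the spectrum", {
  p <- quiet_profile(constriction_amp_mm = c(0, 0),
                     band_osc_amp_mm = data.frame(freq_hz = 2.1,
                                                  amp_mean = 0.4, amp_sd = 0))
  sch <- build_schedule("pro_saccade", 10, seed = 1)
  set.seed(4)
  sig <- synth_pupil_signal(p, sch, 120)
  sp <- compute_spectrum(sig$left[1:1200], 120)
  expect_equal(sp$amplitude[sp$frequency_hz == 2.1], 0.4, tolerance = 0.02)
})

test_that("constriction dip reaches baseline minus depth in the locked mean", {
  p <- quiet_profile(pupil_baseline_mm = c(3.5, 0),
                     constriction_amp_mm = c(0.5, 0),
                     band_osc_amp_mm = data.frame(freq_hz = numeric(0),
                                                  amp_mean = numeric(0),
                                                  amp_sd = numeric(0)))
  sch <- build_schedule("pro_saccade", 10, seed = 1)
  sig <- synth_pupil_signal(p, sch, 120)
  fs <- 120; win <- as.integer(4.2 * fs)
  locked <- rowMeans(sapply(sch$fixation_onset_s, function(s0)
    sig$left[(round(s0 * fs) + 1):(round(s0 * fs) + win)]))
  expect_equal(min(locked), 3.0, tolerance = 0.01)
})

test_that("pupil parameters driving non-positive diameter raise an error", {
  p <- quiet_profile(pupil_baseline_mm = c(0.3, 0),
                     constriction_amp_mm = c(0.5, 0))
  sch <- build_schedule("pro_saccade", 10, seed = 1)
  expect_error(synth_pupil_signal(p, sch, 120), "<= 0")
})

test_that("anti error/correction construction is forced at probability 1", {
  prof <- quiet_profile(anti_error_prob = 1, anti_correction_prob = 1)
  cfg <- cohort_config(n_pd = 1, n_control = 1, pd_profile = prof,
                       control_profile = prof, seed = 5)
  s <- simulate_subject("PD", cfg, 21)
  clean <- preprocess_recording(s$recordings$anti_saccade,
                                s$schedules$anti_saccade)
  sc <- score_trials(clean)
  sc <- sc[sc$valid_trial & sc$responded, ]
  expect_true(all(sc$direction_error))
  expect_gt(mean(sc$corrected), 0.9)   # nearly every error followed by a fix
})

test_that("blink_rate 0 yields fully valid recordings", {
  prof <- quiet_profile()
  cfg <- cohort_config(n_pd = 1, n_control = 1, pd_profile = prof,
                       control_profile = prof, seed = 2)
  s <- simulate_subject("control", cfg, 9)
  expect_true(all(s$recordings$pro_saccade$valid_left))
  expect_true(all(s$recordings$anti_saccade$valid_right))
})

test_that("simulate_cohort is deterministic and seed-sensitive", {
  cfg <- small_config(n_pd = 2, n_control = 2, seed = 13)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  expect_equal(nrow(a$subjects), 4L)
  expect_equal(sum(lengths(a$recordings)), 8L)   # 4 subjects x 2 tasks
  c2 <- simulate_cohort(small_config(n_pd = 2, n_control = 2, seed = 14))
  expect_false(identical(
    a$schedules[[1]]$pro_saccade$side, c2$schedules[[1]]$pro_saccade$side))
})

test_that("generated recordings satisfy container invariants", {
  cfg <- small_config(n_pd = 2, n_control = 1, seed = 3)
  co <- simulate_cohort(cfg)
  for (id in names(co$recordings)) for (task in task_types()) {
    r <- co$recordings[[id]][[task]]
    expect_s3_class(r, "gaze_recording")
    expect_true(all(diff(r$t) > 0))
    expect_true(all(r$pupil_left_mm[r$valid_left] > 0))
    expect_equal(length(r$t), length(r$gaze_x_deg))
  }
})

test_that("scored latency recovers the generating latency mean", {
  # single-task scoring over many subjects; latency draws are shifted-gamma
  # with exact mean, so the scored mean must sit within 2 SEM of the profile
  prof <- quiet_profile(latency_ms = c(270, 115))
  cfg <- cohort_config(n_pd = 30, n_control = 1, pd_profile = prof,
                       control_profile = prof, seed = 41)
  lat <- c()
  for (i in seq_len(30)) {
    s <- simulate_subject("PD", cfg, 1000 + i)
    clean <- preprocess_recording(s$recordings$pro_saccade,
                                  s$schedules$pro_saccade)
    sc <- score_trials(clean)
    lat <- c(lat, sc$first_saccade_latency_ms[sc$valid_trial & sc$responded])
  }
  # conservative subject-level SEM: total trial SD over sqrt(n subjects)
  expect_lt(abs(mean(lat) - 270), 2 * sd(lat) / sqrt(30))
})
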