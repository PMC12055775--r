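# Shared fixture builders. All fixtures are generated in code; the min-jerk
# shape here is written out independently of the package internals so traces
# used as detector input double as an oracle of the generator.

FS <- 120

# quintic minimum-jerk position shape (independent reimplementation)
mj_shape <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}

# Build a gaze trace from a list of saccades: each list(onset, amp, vp).
# Returns the position vector on an n-sample grid at fs Hz.
make_gaze <- function(saccades, n, fs = FS) {
  t <- (seq_len(n) - 1) / fs
  x <- numeric(n)
  for (s in saccades) {
    D <- 1.875 * abs(s$amp) / s$vp
    x <- x + s$amp * mj_shape((t - s$onset) / D)
  }
  x
}

make_recording <- function(x, fs = FS, pupil = 3.5, valid = TRUE,
                           task = "pro_saccade", group = "PD",
                           subject_id = "fix") {
  n <- length(x)
  gaze_recording(subject_id = subject_id, group = group, task = task,
                 sample_rate_hz = fs, t = (seq_len(n) - 1) / fs,
                 gaze_x_deg = x,
                 pupil_left_mm = rep_len(pupil, n),
                 pupil_right_mm = rep_len(pupil, n),
                 valid_left = rep_len(valid, n),
                 valid_right = rep_len(valid, n))
}

# a small quiet profile: no blinks, no noise -- deterministic behaviour tests
quiet_profile <- function(...) {
  p <- default_control_profile()
  p$blink_rate_hz <- 0
  p$noise_sd_mm <- 0
  dots <- list(...)
  for (nm in names(dots)) p[[nm]] <- dots[[nm]]
  p
}

small_config <- function(n_pd = 3L, n_control = 3L, seed = 7L, ...) {
  cohort_config(n_pd = n_pd, n_control = n_control, seed = seed, ...)
}

# Brute-force saccade detector: explicit per-sample state machine with the
# same thresholds; independent of the vectorized implementation.
oracle_detect <- function(x, fs, onset_thresh = 30, offset_thresh = 20,
                          min_dur_ms = 10, min_amp_deg = 1) {
  n <- length(x)
  v <- numeric(n - 1)
  for (k in seq_len(n - 1)) v[k] <- (x[k + 1] - x[k]) * fs
  # 5-point quadratic Savitzky-Golay smoothing, looped
  w <- c(-3, 12, 17, 12, -3) / 35
  vs <- v
  if (length(v) >= 5) for (k in 3:(length(v) - 2)) vs[k] <- sum(w * v[(k - 2):(k + 2)])
  events <- list()
  k <- 1
  while (k <= length(vs)) {
    if (abs(vs[k]) >= onset_thresh) {
      a <- k; b <- k
      while (a > 1 && abs(vs[a - 1]) >= offset_thresh) a <- a - 1
      while (b < length(vs) && abs(vs[b + 1]) >= offset_thresh) b <- b + 1
      amp <- x[b + 1] - x[a]
      dur_ms <- (b + 1 - a) / fs * 1000
      if (dur_ms >= min_dur_ms && abs(amp) >= min_amp_deg)
        events[[length(events) + 1]] <- c(onset_idx = a, offset_idx = b + 1,
                                          amp = amp)
      k <- b + 1
    }
    k <- k + 1
  }
  events
}
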