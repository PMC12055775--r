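# Synthetic cohort generator.
#
# Emulates the VR pro-/anti-saccade protocol: per-trial minimum-jerk saccades
# with group-dependent latency, gain and peak velocity; direction errors and
# corrective saccades on anti trials; stimulus-locked pupil constriction with
# band-structured sinusoidal oscillations; Poisson blinks zeroing validity.

# Hard physiological bounds used when drawing kinematic parameters. The peak
# velocity ceiling also keeps saccades resolvable at the 120 Hz default rate
# (a 10 deg saccade at 650 deg/s spans ~3.5 samples, the practical limit for
# 5%-accurate peak-velocity recovery with spline-refined differentiation).
.LIMITS <- list(
  latency_floor_ms = 100, latency_within_ms = 40,
  vel_lo_dps = 150, vel_hi_dps = 650, vel_within_dps = 40,
  gain_lo = 0.5, gain_hi = 1.15,
  corr_delay_floor_ms = 80,
  isi_mean_ms = 150, isi_sd_ms = 30,
  blink_min_s = 0.1, blink_max_s = 0.3
)

#' Group-level generating profile
#'
#' Parameter set describing one diagnostic group's oculomotor and pupillary
#' behaviour. Mean/SD pairs are length-2 numeric vectors `c(mean, sd)`.
#'
#' @param latency_ms Saccade latency (ms), mean and SD across subjects.
#' @param peak_velocity_dps Saccade peak velocity (deg/s), mean and SD.
#' @param gain Primary-saccade gain (landing amplitude / target
#'   eccentricity), mean and SD.
#' @param pro_correct_prob Probability a pro-saccade trial starts with a
#'   stimulus-ward saccade.
#' @param anti_error_prob Probability an anti-saccade trial starts with an
#'   erroneous stimulus-ward saccade.
#' @param anti_correction_prob Probability a direction error is followed by a
#'   corrective saccade to the mirror location.
#' @param correction_delay_ms Error-saccade offset to corrective-saccade
#'   onset (ms), mean and SD.
#' @param pupil_baseline_mm Baseline pupil diameter (mm), mean and SD.
#' @param constriction_amp_mm Depth of the stimulus-locked constriction dip
#'   (mm), mean and SD.
#' @param band_osc_amp_mm Data frame with columns `freq_hz`, `amp_mean`,
#'   `amp_sd`: stationary sinusoidal pupil oscillations (mm amplitude) at
#'   fixed frequencies in the range 0-19 Hz.
#' @param noise_sd_mm White measurement noise SD on pupil channels (mm).
#' @param blink_rate_hz Poisson blink rate (events per second).
#' @return A `group_profile` list.
#' @export
group_profile <- function(latency_ms, peak_velocity_dps, gain,
                          pro_correct_prob, anti_error_prob,
                          anti_correction_prob, correction_delay_ms,
                          pupil_baseline_mm, constriction_amp_mm,
                          band_osc_amp_mm, noise_sd_mm, blink_rate_hz) {
  p <- list(latency_ms = latency_ms, peak_velocity_dps = peak_velocity_dps,
            gain = gain, pro_correct_prob = pro_correct_prob,
            anti_error_prob = anti_error_prob,
            anti_correction_prob = anti_correction_prob,
            correction_delay_ms = correction_delay_ms,
            pupil_baseline_mm = pupil_baseline_mm,
            constriction_amp_mm = constriction_amp_mm,
            band_osc_amp_mm = band_osc_amp_mm,
            noise_sd_mm = noise_sd_mm, blink_rate_hz = blink_rate_hz)
  for (f in c("latency_ms", "peak_velocity_dps", "gain", "correction_delay_ms",
              "pupil_baseline_mm", "constriction_amp_mm")) {
    v <- p[[f]]
    if (length(v) != 2L || v[2] < 0) stop(f, " must be c(mean, sd) with sd >= 0")
  }
  for (f in c("pro_correct_prob", "anti_error_prob", "anti_correction_prob")) {
    v <- p[[f]]
    if (length(v) != 1L || v < 0 || v > 1) stop(f, " must be a probability")
  }
  b <- p$band_osc_amp_mm
  stopifnot(is.data.frame(b),
            all(c("freq_hz", "amp_mean", "amp_sd") %in% names(b)))
  if (nrow(b) && (any(b$freq_hz < 0) || any(b$freq_hz > 19)))
    stop("band oscillation frequencies must lie in the range 0-19 Hz")
  if (p$noise_sd_mm < 0 || p$blink_rate_hz < 0)
    stop("noise_sd_mm and blink_rate_hz must be >= 0")
  structure(p, class = "group_profile")
}

#' Default generating profiles
#'
#' Group profiles anchored to the published early-PD vs control summary
#' scale: saccadic parameter means/SDs from the group comparison table
#' (latency, peak velocity, behavioural rates, correction delay) and pupil
#' band-oscillation amplitudes from the anti-saccade frequency-amplitude
#' table (2.1 / 11.8 / 17.4 Hz). Illustrative of the reported contrasts, not
#' a claim of fidelity to the private clinical recordings.
#'
#' @return A `group_profile`.
#' @export
default_pd_profile <- function() {
  group_profile(
    latency_ms = c(269.5, 116.4),
    peak_velocity_dps = c(424.3, 197.9),
    gain = c(0.85, 0.10),
    pro_correct_prob = 0.848,
    anti_error_prob = 0.575,
    anti_correction_prob = 0.268,
    correction_delay_ms = c(247.1, 236.8),
    pupil_baseline_mm = c(3.6, 0.4),
    constriction_amp_mm = c(0.30, 0.08),
    band_osc_amp_mm = data.frame(
      freq_hz = c(2.1, 11.8, 17.4),
      amp_mean = c(0.48, 0.10, 0.07),
      amp_sd = c(0.12, 0.04, 0.03)),
    noise_sd_mm = 0.05,
    blink_rate_hz = 0.08
  )
}

#' @rdname default_pd_profile
#' @export
default_control_profile <- function() {
  group_profile(
    latency_ms = c(283.3, 100.3),
    peak_velocity_dps = c(536.5, 141.6),
    gain = c(0.95, 0.07),
    pro_correct_prob = 0.933,
    anti_error_prob = 0.622,
    anti_correction_prob = 0.451,
    correction_delay_ms = c(310.0, 191.6),
    pupil_baseline_mm = c(3.9, 0.4),
    constriction_amp_mm = c(0.30, 0.08),
    band_osc_amp_mm = data.frame(
      freq_hz = c(2.1, 11.8, 17.4),
      amp_mean = c(0.25, 0.17, 0.12),
      amp_sd = c(0.08, 0.05, 0.04)),
    noise_sd_mm = 0.05,
    blink_rate_hz = 0.08
  )
}

#' Cohort configuration
#'
#' @param n_pd,n_control Group sizes (defaults 43 and 25, the study cohort).
#' @param pd_profile,control_profile `group_profile` objects.
#' @param sample_rate_hz Recording sample rate, Hz (default 120).
#' @param eccentricity_deg Stimulus eccentricity, degrees (default 10).
#' @param seed Root seed; all subject-level seeds derive from it.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_pd = 43L, n_control = 25L,
                          pd_profile = default_pd_profile(),
                          control_profile = default_control_profile(),
                          sample_rate_hz = 120, eccentricity_deg = 10,
                          seed = 1L) {
  stopifnot(n_pd >= 1L, n_control >= 1L, sample_rate_hz > 0,
            eccentricity_deg > 0,
            inherits(pd_profile, "group_profile"),
            inherits(control_profile, "group_profile"))
  structure(list(n_pd = as.integer(n_pd), n_control = as.integer(n_control),
                 pd_profile = pd_profile, control_profile = control_profile,
                 sample_rate_hz = sample_rate_hz,
                 eccentricity_deg = eccentricity_deg,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# ---- primitive draws --------------------------------------------------------

# Truncated normal via inverse CDF (fixed RNG consumption per draw).
rtnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  mean <- rep_len(mean, n); sd <- rep_len(sd, n)
  out <- numeric(n)
  pos <- sd > 0
  out[!pos] <- pmin(pmax(mean[!pos], lo), hi)
  if (any(pos)) {
    plo <- pnorm(lo, mean[pos], sd[pos]); phi <- pnorm(hi, mean[pos], sd[pos])
    out[pos] <- stats::qnorm(runif(sum(pos), plo, phi), mean[pos], sd[pos])
  }
  out
}

# Shifted gamma matched to (mean, sd): support (shift, Inf), exact mean.
rgamma_shift <- function(n, mean, sd, shift) {
  m <- mean - shift
  if (m <= 0) stop("mean must exceed shift for a shifted-gamma draw")
  if (sd <= 0) return(rep(mean, n))
  shape <- (m / sd)^2
  shift + rgamma(n, shape = shape, scale = m / shape)
}

# ---- saccade waveform -------------------------------------------------------

# Minimum-jerk unit shape s(tau) = 10 tau^3 - 15 tau^4 + 6 tau^5 on [0, 1].
min_jerk_shape <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  tau^3 * (10 + tau * (-15 + 6 * tau))
}

#' Synthesize a minimum-jerk saccade waveform
#'
#' Generates the gaze-angle segment of a single saccade with a minimum-jerk
#' position profile. Duration follows from the closed-form minimum-jerk
#' relation `duration = 1.875 * |amplitude| / peak_velocity`.
#'
#' @param amplitude_deg Signed saccade amplitude, degrees (non-zero).
#' @param peak_velocity_dps Peak angular velocity, deg/s (> 0).
#' @param onset_s Saccade onset time, seconds.
#' @param sample_rate Sampling rate, Hz.
#' @return List with `t` (sample times spanning the saccade), `x`
#'   (displacement from 0 to `amplitude_deg`), and `duration_s`.
#' @examples
#' w <- synth_saccade_waveform(10, 400, 0, 120)
#' w$duration_s  # ~0.0469 s
#' @export
synth_saccade_waveform <- function(amplitude_deg, peak_velocity_dps, onset_s,
                                   sample_rate) {
  if (!is.finite(amplitude_deg) || amplitude_deg == 0)
    stop("amplitude must be non-zero", call. = FALSE)
  if (!is.finite(peak_velocity_dps) || peak_velocity_dps <= 0)
    stop("peak velocity must be > 0", call. = FALSE)
  dur <- 1.875 * abs(amplitude_deg) / peak_velocity_dps
  if (dur < 2 / sample_rate)
    stop("peak velocity implies duration below 2 samples", call. = FALSE)
  t <- onset_s + seq(0, dur, by = 1 / sample_rate)
  if (t[length(t)] < onset_s + dur) t <- c(t, onset_s + dur)
  list(t = t, x = amplitude_deg * min_jerk_shape((t - onset_s) / dur),
       duration_s = dur)
}

# ---- pupil trace ------------------------------------------------------------

# Raised-sine constriction kernel: dip of unit depth over `len_s` seconds.
constriction_kernel <- function(u, len_s = 1.8) {
  ifelse(u >= 0 & u <= len_s, sin(pi * u / len_s)^2, 0)
}

#' Synthesize one task's pupil-diameter traces
#'
#' Builds left/right pupil traces as baseline + stimulus-locked constriction
#' dips (depth `constriction_amp_mm`, beginning at each stimulus onset and
#' recovering during rest) + stationary sinusoids at the profile's band
#' frequencies (random phases, independent per eye) + white noise.
#'
#' @param profile A `group_profile`; mean values are used as the subject's
#'   effective parameters (draw subject-level profiles upstream).
#' @param schedule A `stimulus_schedule`.
#' @param sample_rate Sampling rate, Hz.
#' @return List with `t`, `left`, `right` (mm).
#' @export
synth_pupil_signal <- function(profile, schedule, sample_rate) {
  stopifnot(inherits(profile, "group_profile"),
            inherits(schedule, "stimulus_schedule"))
  dur <- if (nrow(schedule)) max(schedule$rest_end_s) else 0
  t <- seq(0, dur - 1 / sample_rate, by = 1 / sample_rate)
  base <- profile$pupil_baseline_mm[1]
  depth <- profile$constriction_amp_mm[1]
  if (base - depth - 3 * profile$noise_sd_mm <= 0)
    stop("profile drives pupil diameter <= 0", call. = FALSE)
  dip <- numeric(length(t))
  for (s0 in schedule$stimulus_onset_s)
    dip <- dip + constriction_kernel(t - s0)
  make_eye <- function() {
    x <- base - depth * dip
    b <- profile$band_osc_amp_mm
    if (nrow(b)) {
      phases <- runif(nrow(b), 0, 2 * pi)
      for (i in seq_len(nrow(b)))
        x <- x + b$amp_mean[i] * sin(2 * pi * b$freq_hz[i] * t + phases[i])
    }
    if (profile$noise_sd_mm > 0) x <- x + rnorm(length(t), 0, profile$noise_sd_mm)
    x
  }
  left <- make_eye(); right <- make_eye()
  if (length(t) && (min(left) <= 0 || min(right) <= 0))
    stop("generated pupil trace reached <= 0 mm; reduce oscillation/noise amplitudes",
         call. = FALSE)
  list(t = t, left = left, right = right)
}

# ---- subject simulation -----------------------------------------------------

# Subject-level effective parameters drawn from a group profile.
draw_subject_params <- function(profile) {
  L <- .LIMITS
  bsd <- function(v, within) sqrt(max(v[2]^2 - within^2, (0.2 * v[2])^2))
  band <- profile$band_osc_amp_mm
  band$amp <- if (nrow(band))
    rtnorm(nrow(band), band$amp_mean, band$amp_sd, 0.005, 2) else numeric(0)
  list(
    latency_ms = rgamma_shift(1, profile$latency_ms[1],
                              bsd(profile$latency_ms, L$latency_within_ms),
                              L$latency_floor_ms),
    peak_velocity_dps = rtnorm(1, profile$peak_velocity_dps[1],
                               bsd(profile$peak_velocity_dps, L$vel_within_dps),
                               L$vel_lo_dps, L$vel_hi_dps),
    gain = rtnorm(1, profile$gain[1], 0.7 * profile$gain[2],
                  L$gain_lo, L$gain_hi),
    correction_delay_ms = rgamma_shift(1, profile$correction_delay_ms[1],
                                       max(profile$correction_delay_ms[2], 1),
                                       L$corr_delay_floor_ms),
    pupil_baseline_mm = rtnorm(1, profile$pupil_baseline_mm[1],
                               profile$pupil_baseline_mm[2], 2.2, 6.5),
    constriction_amp_mm = rtnorm(1, profile$constriction_amp_mm[1],
                                 profile$constriction_amp_mm[2], 0.05, 1),
    band_amp = band$amp
  )
}

# Add a saccade as position increments into the accumulator dx (the gaze
# trace is cumsum(dx)); touches only the saccade's own samples.
# Returns list(dx, onset_s, offset_s, landing).
add_saccade <- function(dx, t, fs, onset_s, from, to, vp) {
  A <- to - from
  if (abs(A) < 1e-6) return(list(dx = dx, onset_s = onset_s, offset_s = onset_s,
                                 landing = from))
  vp <- min(vp, 1.875 * abs(A) * fs / 3)  # keep >= 3 samples
  dur <- 1.875 * abs(A) / vp
  n <- length(dx)
  i0 <- max(1L, as.integer(floor(onset_s * fs)) + 1L)
  i1 <- min(n, as.integer(ceiling((onset_s + dur) * fs)) + 2L)
  if (i0 > n) return(list(dx = dx, onset_s = onset_s, offset_s = onset_s + dur,
                          landing = to))
  sh <- min_jerk_shape((t[i0:i1] - onset_s) / dur)
  prev <- if (i0 > 1L) min_jerk_shape((t[i0 - 1L] - onset_s) / dur) else 0
  dx[i0:i1] <- dx[i0:i1] + A * diff(c(prev, sh))
  if (i1 < n) {
    # remainder of the displacement lands on the sample after the window
    dx[i1 + 1L] <- dx[i1 + 1L] + A * (1 - sh[length(sh)])
  }
  list(dx = dx, onset_s = onset_s, offset_s = onset_s + dur, landing = to)
}

#' Simulate one subject
#'
#' Generates both task recordings for one subject: per-trial behavioural
#' draws (latency, gain, peak velocity; pro correctness, anti direction
#' errors and corrections), minimum-jerk saccades with corrective follow-ups
#' when the primary saccade lands short of the goal, pupil traces from
#' [synth_pupil_signal()], and Poisson blinks zeroing validity for 100-300 ms.
#'
#' @param group `"PD"` or `"control"`.
#' @param config A `cohort_config`.
#' @param subject_seed Integer seed for this subject.
#' @param subject_id Identifier string.
#' @return List with `recordings` (named by task: `gaze_recording`),
#'   `schedules` (named by task), and `truth` (subject-level generating
#'   parameters).
#' @export
simulate_subject <- function(group, config, subject_seed,
                             subject_id = sprintf("%s_s%d", group, subject_seed)) {
  stopifnot(inherits(config, "cohort_config"), group %in% c("PD", "control"))
  profile <- if (group == "PD") config$pd_profile else config$control_profile
  L <- .LIMITS
  fs <- config$sample_rate_hz
  ecc <- config$eccentricity_deg
  old <- local_seed(as.integer(subject_seed))
  on.exit(restore_seed(old))

  sp <- draw_subject_params(profile)
  recs <- list(); schs <- list()
  for (task in task_types()) {
    sch_seed <- sample.int(.Machine$integer.max, 1L)
    sch <- build_schedule(task, ecc, seed = sch_seed)
    n <- as.integer(round(max(sch$rest_end_s) * fs))
    t <- (seq_len(n) - 1) / fs
    dx <- numeric(n)
    cur <- 0; last_off <- -Inf
    for (k in seq_len(nrow(sch))) {
      side <- if (sch$side[k] == "right") 1 else -1
      stim_on <- sch$stimulus_onset_s[k]
      stim_off <- sch$stimulus_offset_s[k]
      lat <- rgamma_shift(1, sp$latency_ms, L$latency_within_ms,
                          L$latency_floor_ms) / 1000
      vp <- rtnorm(1, sp$peak_velocity_dps, L$vel_within_dps,
                   L$vel_lo_dps, L$vel_hi_dps)
      g <- rtnorm(1, sp$gain, 0.7 * profile$gain[2], L$gain_lo, L$gain_hi)
      if (task == "pro_saccade") {
        correct_dir <- runif(1) < profile$pro_correct_prob
        dir_sign <- if (correct_dir) side else -side
        goal <- side * ecc       # instructed goal
      } else {
        err <- runif(1) < profile$anti_error_prob
        dir_sign <- if (err) side else -side
        goal <- -side * ecc
      }
      onset <- max(stim_on + lat, last_off + 2 / fs)
      sac <- add_saccade(dx, t, fs, onset, cur, dir_sign * ecc * g, vp)
      dx <- sac$dx; cur <- sac$landing; last_off <- sac$offset_s
      toward_goal <- sign(goal) == sign(cur)
      if (task == "anti_saccade" && !toward_goal) {
        # direction error; corrective saccade with group probability
        if (runif(1) < profile$anti_correction_prob) {
          cd <- rgamma_shift(1, sp$correction_delay_ms,
                             max(profile$correction_delay_ms[2] / 2, 1),
                             L$corr_delay_floor_ms) / 1000
          g2 <- rtnorm(1, 0.95, 0.04, 0.8, 1.1)
          vp2 <- rtnorm(1, sp$peak_velocity_dps, L$vel_within_dps,
                        L$vel_lo_dps, L$vel_hi_dps)
          sac <- add_saccade(dx, t, fs, last_off + cd, cur, goal * g2, vp2)
          dx <- sac$dx; cur <- sac$landing; last_off <- sac$offset_s
        }
      } else if (toward_goal && abs(cur - goal) > 1.0) {
        # hypometric primary: corrective saccade after an intersaccadic pause
        isi <- rtnorm(1, L$isi_mean_ms, L$isi_sd_ms, 80, 300) / 1000
        g2 <- rtnorm(1, 0.95, 0.04, 0.8, 1.1)
        vp2 <- rtnorm(1, sp$peak_velocity_dps, L$vel_within_dps,
                      L$vel_lo_dps, L$vel_hi_dps)
        sac <- add_saccade(dx, t, fs, last_off + isi, cur,
                           cur + (goal - cur) * g2, vp2)
        dx <- sac$dx; cur <- sac$landing; last_off <- sac$offset_s
      }
      # return to central fixation during rest
      ret_on <- min(max(last_off + 0.30, stim_off + 0.40),
                    sch$rest_end_s[k] - 0.30)
      ret_on <- max(ret_on, last_off + 2 / fs)
      vp3 <- rtnorm(1, sp$peak_velocity_dps, L$vel_within_dps,
                    L$vel_lo_dps, L$vel_hi_dps)
      sac <- add_saccade(dx, t, fs, ret_on, cur, 0, vp3)
      dx <- sac$dx; cur <- sac$landing; last_off <- sac$offset_s
    }
    x <- cumsum(dx)

    eff <- profile
    eff$pupil_baseline_mm <- c(sp$pupil_baseline_mm, 0)
    eff$constriction_amp_mm <- c(sp$constriction_amp_mm, 0)
    if (nrow(eff$band_osc_amp_mm)) eff$band_osc_amp_mm$amp_mean <- sp$band_amp
    pup <- synth_pupil_signal(eff, sch, fs)

    valid <- rep(TRUE, n)
    pl <- pup$left[seq_len(n)]; pr <- pup$right[seq_len(n)]
    if (profile$blink_rate_hz > 0) {
      nb <- rpois(1, profile$blink_rate_hz * n / fs)
      if (nb > 0) {
        b_on <- runif(nb, 0, n / fs)
        b_dur <- runif(nb, L$blink_min_s, L$blink_max_s)
        for (j in seq_len(nb)) {
          idx <- which(t >= b_on[j] & t < b_on[j] + b_dur[j])
          valid[idx] <- FALSE
          pl[idx] <- 0; pr[idx] <- 0
        }
      }
    }
    recs[[task]] <- gaze_recording(
      subject_id = subject_id, group = group, task = task,
      sample_rate_hz = fs, t = t, gaze_x_deg = x,
      pupil_left_mm = pl, pupil_right_mm = pr,
      valid_left = valid, valid_right = valid)
    schs[[task]] <- sch
  }
  truth <- data.frame(subject_id = subject_id, group = group,
                      latency_ms = sp$latency_ms,
                      peak_velocity_dps = sp$peak_velocity_dps,
                      gain = sp$gain,
                      correction_delay_ms = sp$correction_delay_ms,
                      pupil_baseline_mm = sp$pupil_baseline_mm,
                      constriction_amp_mm = sp$constriction_amp_mm,
                      stringsAsFactors = FALSE)
  list(recordings = recs, schedules = schs, truth = truth)
}

#' Simulate a full cohort
#'
#' Deterministic given `config$seed`: subject seeds are drawn once from the
#' root seed, then each subject is generated independently.
#'
#' @param config A `cohort_config`.
#' @return A `cohort` object: list with `subjects` (data.frame of ids,
#'   groups, seeds), `recordings` (`recordings[[subject_id]][[task]]`),
#'   `schedules` (parallel structure), `truth` (subject-level generating
#'   parameters), and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_pd + config$n_control
  old <- local_seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  restore_seed(old)
  groups <- c(rep("PD", config$n_pd), rep("control", config$n_control))
  ids <- c(sprintf("pd%02d", seq_len(config$n_pd)),
           sprintf("hc%02d", seq_len(config$n_control)))
  recordings <- list(); schedules <- list(); truth <- list()
  for (i in seq_len(n)) {
    s <- simulate_subject(groups[i], config, seeds[i], subject_id = ids[i])
    recordings[[ids[i]]] <- s$recordings
    schedules[[ids[i]]] <- s$schedules
    truth[[i]] <- s$truth
  }
  structure(list(
    subjects = data.frame(subject_id = ids, group = groups, seed = seeds,
                          stringsAsFactors = FALSE),
    recordings = recordings, schedules = schedules,
    truth = do.call(rbind, truth), config = config
  ), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d PD + %d control subjects, %d recordings @ %g Hz\n",
              sum(x$subjects$group == "PD"),
              sum(x$subjects$group == "control"),
              sum(lengths(x$recordings)), x$config$sample_rate_hz))
  invisible(x)
}
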