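# Blink/artifact handling: flag bad samples, interpolate short pupil gaps,
# exclude trials with long gaps in their scoring-critical span.

#' Detect artifact samples
#'
#' Flags samples that are tracker-invalid, have pupil diameter outside
#' physiological bounds, or exceed a pupil slew limit (|d pupil / dt|).
#' Flags are computed per eye; a sample is gap-flagged when either eye is bad.
#'
#' @param rec A `gaze_recording`.
#' @param max_gap_ms Unused by detection itself; retained so the
#'   detect/repair pair shares a parameter surface. Default 75.
#' @param pupil_bounds_mm Length-2 numeric, plausible pupil range in mm.
#'   Default `c(1.5, 9)`.
#' @param slew_limit_mm_s Maximum physiological pupil rate of change, mm/s.
#'   Default 10.
#' @return An `artifact_mask`: list with logical matrices-by-eye (`left`,
#'   `right`), combined logical `bad`, a character `reason` per flagged
#'   sample (`tracker_invalid`, `off_scale`, `slew`), and a `gaps`
#'   data.frame (`start_idx`, `end_idx`, `start_s`, `end_s`, `duration_ms`,
#'   `reason`) of contiguous flagged runs.
#' @export
detect_artifacts <- function(rec, max_gap_ms = 75,
                             pupil_bounds_mm = c(1.5, 9),
                             slew_limit_mm_s = 10) {
  stopifnot(inherits(rec, "gaze_recording"))
  fs <- rec$sample_rate_hz
  # slew is judged on a ~250 ms moving average: band oscillations and sample
  # noise are signal here, the limit targets gross tracker glitches/blinks
  ma_n <- max(3L, as.integer(round(0.25 * fs)))
  flag_eye <- function(p, valid) {
    bad_valid <- !valid
    bad_scale <- !bad_valid & (p < pupil_bounds_mm[1] | p > pupil_bounds_mm[2])
    # bridge invalid samples before averaging so blink zeros do not bleed
    # slew flags into the surrounding valid data
    pb <- p
    if (any(bad_valid) && any(!bad_valid)) {
      good <- which(!bad_valid)
      pb <- approx(good, p[good], xout = seq_along(p), rule = 2)$y
    }
    pm <- as.numeric(stats::filter(pb, rep(1 / ma_n, ma_n), sides = 2))
    pm[is.na(pm)] <- pb[is.na(pm)]
    slew <- c(0, abs(diff(pm)) * fs)
    bad_slew <- !bad_valid & !bad_scale & slew > slew_limit_mm_s
    # slew flags the sample after an implausible jump; also flag the jump's
    # other endpoint so isolated spikes are fully covered
    bad_slew <- bad_slew | c(bad_slew[-1], FALSE)
    reason <- rep(NA_character_, length(p))
    reason[bad_slew] <- "slew"
    reason[bad_scale] <- "off_scale"
    reason[bad_valid] <- "tracker_invalid"
    list(bad = bad_valid | bad_scale | bad_slew, reason = reason)
  }
  L <- flag_eye(rec$pupil_left_mm, rec$valid_left)
  R <- flag_eye(rec$pupil_right_mm, rec$valid_right)
  bad <- L$bad | R$bad
  reason <- ifelse(!is.na(L$reason), L$reason, R$reason)
  gaps <- runs_of(bad)
  if (nrow(gaps)) {
    gaps$start_s <- rec$t[gaps$start_idx]
    gaps$end_s <- rec$t[gaps$end_idx] + 1 / fs
    gaps$duration_ms <- 1000 * (gaps$end_idx - gaps$start_idx + 1L) / fs
    gaps$reason <- vapply(seq_len(nrow(gaps)), function(i) {
      r <- reason[gaps$start_idx[i]:gaps$end_idx[i]]
      r <- r[!is.na(r)]
      if (!length(r)) "tracker_invalid" else names(sort(table(r), decreasing = TRUE))[1]
    }, character(1))
    # blink-length tracker dropouts are blink gaps by convention
    gaps$reason[gaps$reason == "tracker_invalid"] <- "blink_gap"
    gaps$reason[gaps$reason == "slew"] <- "off_scale"
  }
  structure(list(left = L$bad, right = R$bad, bad = bad,
                 reason = reason, gaps = gaps,
                 params = list(max_gap_ms = max_gap_ms,
                               pupil_bounds_mm = pupil_bounds_mm,
                               slew_limit_mm_s = slew_limit_mm_s)),
            class = "artifact_mask")
}

# Contiguous TRUE runs of a logical vector -> data.frame(start_idx, end_idx).
runs_of <- function(bad) {
  if (!any(bad)) return(data.frame(start_idx = integer(0), end_idx = integer(0)))
  r <- rle(bad)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start_idx = starts[r$values], end_idx = ends[r$values])
}

#' Repair short gaps and exclude unusable trials
#'
#' Pupil channels are linearly interpolated across gaps no longer than
#' `max_interp_ms`. Trials whose fixation-through-stimulus span contains a
#' longer gap are excluded (gaze channels are never interpolated, which
#' would fabricate saccades). Edge gaps that cannot be interpolated are
#' held at the nearest good value for spectral continuity but still force
#' trial exclusion when long.
#'
#' @param rec A `gaze_recording`.
#' @param mask An `artifact_mask` from [detect_artifacts()].
#' @param schedule The trial schedule used to localize exclusions.
#' @param max_interp_ms Longest gap (ms) eligible for interpolation.
#'   Default 75.
#' @return A `clean_recording`: the recording with repaired pupil channels,
#'   plus `mask`, `excluded_trials` (data.frame `trial_index`, `reason`),
#'   and `kept_trials`.
#' @export
repair_or_exclude <- function(rec, mask, schedule, max_interp_ms = 75) {
  stopifnot(inherits(rec, "gaze_recording"), inherits(mask, "artifact_mask"),
            inherits(schedule, "stimulus_schedule"))
  fs <- rec$sample_rate_hz
  interp_eye <- function(p, bad) {
    if (!any(bad)) return(p)
    good <- which(!bad)
    if (!length(good)) return(p)
    # rule = 2: edge gaps held at nearest good value
    approx(rec$t[good], p[good], xout = rec$t, rule = 2)$y
  }
  pl <- interp_eye(rec$pupil_left_mm, mask$left)
  pr <- interp_eye(rec$pupil_right_mm, mask$right)

  long <- mask$gaps[mask$gaps$duration_ms > max_interp_ms, , drop = FALSE]
  excl <- data.frame(trial_index = integer(0), reason = character(0),
                     stringsAsFactors = FALSE)
  if (nrow(long) && nrow(schedule)) {
    for (k in seq_len(nrow(schedule))) {
      # scoring-critical span: fixation onset through stimulus offset
      w0 <- schedule$fixation_onset_s[k]; w1 <- schedule$stimulus_offset_s[k]
      hit <- long$start_s < w1 & long$end_s > w0
      if (any(hit))
        excl <- rbind(excl, data.frame(
          trial_index = schedule$index[k],
          reason = long$reason[which(hit)[1]], stringsAsFactors = FALSE))
    }
  }
  out <- rec
  out$pupil_left_mm <- pl
  out$pupil_right_mm <- pr
  out$mask <- mask
  out$max_interp_ms <- max_interp_ms
  out$excluded_trials <- excl
  out$kept_trials <- setdiff(schedule$index, excl$trial_index)
  out$schedule <- schedule
  class(out) <- c("clean_recording", "gaze_recording")
  out
}

#' One-call preprocessing
#'
#' @inheritParams repair_or_exclude
#' @inheritParams detect_artifacts
#' @return A `clean_recording`.
#' @export
preprocess_recording <- function(rec, schedule, max_interp_ms = 75,
                                 pupil_bounds_mm = c(1.5, 9),
                                 slew_limit_mm_s = 10) {
  if (inherits(rec, "clean_recording")) return(rec)
  mask <- detect_artifacts(rec, max_interp_ms, pupil_bounds_mm, slew_limit_mm_s)
  repair_or_exclude(rec, mask, schedule, max_interp_ms)
}

#' @export
print.clean_recording <- function(x, ...) {
  cat(sprintf("<clean_recording> %s [%s] %s: %d/%d trials kept, %d artifact gaps\n",
              x$subject_id, x$group, x$task, length(x$kept_trials),
              nrow(x$schedule), nrow(x$mask$gaps)))
  invisible(x)
}
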