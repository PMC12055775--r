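# Task protocol: trial timing, stimulus schedules, recording containers.
#
# Timing per trial: 1 s central fixation, 1.2 s lateral stimulus, 2 s rest.
# 40 trials per task (20 per side, order randomized). All times in seconds
# from recording start; trial windows are half-open [start, end).

TRIAL_FIXATION_S <- 1.0
TRIAL_STIMULUS_S <- 1.2
TRIAL_REST_S     <- 2.0
TRIAL_TOTAL_S    <- TRIAL_FIXATION_S + TRIAL_STIMULUS_S + TRIAL_REST_S
TRIALS_PER_SIDE  <- 20L

#' Task types
#'
#' The two saccade paradigms: `"pro_saccade"` (look toward the stimulus) and
#' `"anti_saccade"` (look to the mirror location opposite the stimulus).
#'
#' @return Character vector of the two valid task identifiers.
#' @export
task_types <- function() c("pro_saccade", "anti_saccade")

assert_task <- function(task) {
  if (!is.character(task) || length(task) != 1L || !task %in% task_types())
    stop("`task` must be one of ", paste(task_types(), collapse = ", "),
         call. = FALSE)
  task
}

#' Build a stimulus schedule for one task
#'
#' Creates the 40-trial schedule (20 left, 20 right, seeded random order) with
#' the canonical trial timing: fixation 1 s, lateral stimulus 1.2 s, rest 2 s.
#'
#' @param task `"pro_saccade"` or `"anti_saccade"`.
#' @param eccentricity_deg Horizontal stimulus eccentricity in degrees of
#'   visual angle (must be > 0). Default 10.
#' @param seed Integer seed controlling the side permutation.
#' @param n_per_side Trials per side; the protocol default is 20.
#' @return A `stimulus_schedule`: a data.frame with one row per trial and
#'   columns `index`, `side`, `fixation_onset_s`, `stimulus_onset_s`,
#'   `stimulus_offset_s`, `rest_end_s`, `target_eccentricity_deg`, plus a
#'   `task` attribute.
#' @examples
#' sch <- build_schedule("pro_saccade", 10, seed = 1)
#' table(sch$side)
#' @export
build_schedule <- function(task, eccentricity_deg = 10, seed = 1L,
                           n_per_side = TRIALS_PER_SIDE) {
  assert_task(task)
  if (!is.numeric(eccentricity_deg) || length(eccentricity_deg) != 1L ||
      !is.finite(eccentricity_deg) || eccentricity_deg <= 0)
    stop("`eccentricity_deg` must be a single positive number", call. = FALSE)
  n_per_side <- as.integer(n_per_side)
  if (n_per_side < 0L) stop("`n_per_side` must be >= 0", call. = FALSE)

  sides <- rep(c("left", "right"), each = n_per_side)
  if (length(sides)) {
    old <- local_seed(as.integer(seed))
    sides <- sides[sample.int(length(sides))]
    restore_seed(old)
  }
  n <- length(sides)
  fixation_onset <- (seq_len(n) - 1) * TRIAL_TOTAL_S
  sch <- data.frame(
    index = seq_len(n) - 1L,
    side = if (n) sides else character(0),
    fixation_onset_s = fixation_onset,
    stimulus_onset_s = fixation_onset + TRIAL_FIXATION_S,
    stimulus_offset_s = fixation_onset + TRIAL_FIXATION_S + TRIAL_STIMULUS_S,
    rest_end_s = seq_len(n) * TRIAL_TOTAL_S,  # exactly the next trial's start
    target_eccentricity_deg = rep(eccentricity_deg, n),
    stringsAsFactors = FALSE
  )
  attr(sch, "task") <- task
  class(sch) <- c("stimulus_schedule", "data.frame")
  validate_schedule(sch)
}

validate_schedule <- function(sch) {
  stopifnot(inherits(sch, "stimulus_schedule"))
  if (nrow(sch)) {
    stopifnot(
      all(abs(sch$stimulus_onset_s - sch$fixation_onset_s - TRIAL_FIXATION_S) < 1e-9),
      all(abs(sch$stimulus_offset_s - sch$stimulus_onset_s - TRIAL_STIMULUS_S) < 1e-9),
      all(abs(sch$rest_end_s - sch$stimulus_offset_s - TRIAL_REST_S) < 1e-9),
      all(sch$side %in% c("left", "right")),
      all(sch$target_eccentricity_deg > 0),
      all(diff(sch$fixation_onset_s) > 0)
    )
  }
  sch
}

#' Trial windows of a schedule
#'
#' @param schedule A `stimulus_schedule`.
#' @return A two-column matrix of half-open `[start_s, end_s)` intervals,
#'   one row per trial, covering fixation onset through rest end.
#' @export
trial_windows <- function(schedule) {
  stopifnot(inherits(schedule, "stimulus_schedule"))
  cbind(start_s = schedule$fixation_onset_s, end_s = schedule$rest_end_s)
}

#' @export
print.stimulus_schedule <- function(x, ...) {
  cat(sprintf("<stimulus_schedule> task=%s, %d trials (%d left / %d right), %.1f s\n",
              attr(x, "task"), nrow(x), sum(x$side == "left"),
              sum(x$side == "right"),
              if (nrow(x)) max(x$rest_end_s) else 0))
  invisible(x)
}

#' Construct a gaze recording
#'
#' Container for one subject x task recording: uniformly sampled horizontal /
#' vertical gaze angle (degrees, rightward/upward positive, 0 = central
#' fixation) and left/right pupil diameter (mm) with per-eye validity flags.
#'
#' @param subject_id Subject identifier string.
#' @param group `"PD"` or `"control"`.
#' @param task Task type.
#' @param sample_rate_hz Sampling rate in Hz.
#' @param t Time grid in seconds (strictly increasing, uniform).
#' @param gaze_x_deg,gaze_y_deg Gaze angles in degrees.
#' @param pupil_left_mm,pupil_right_mm Pupil diameters in mm (> 0 where valid).
#' @param valid_left,valid_right Logical per-sample validity per eye.
#' @return A `gaze_recording` object.
#' @export
gaze_recording <- function(subject_id, group, task, sample_rate_hz, t,
                           gaze_x_deg, gaze_y_deg = rep(0, length(t)),
                           pupil_left_mm, pupil_right_mm,
                           valid_left = rep(TRUE, length(t)),
                           valid_right = rep(TRUE, length(t))) {
  assert_task(task)
  stopifnot(group %in% c("PD", "control"))
  n <- length(t)
  lens <- c(length(gaze_x_deg), length(gaze_y_deg), length(pupil_left_mm),
            length(pupil_right_mm), length(valid_left), length(valid_right))
  if (any(lens != n)) stop("all signal arrays must have length(t)", call. = FALSE)
  if (n >= 2L) {
    dt <- diff(t)
    if (any(dt <= 0) || any(abs(dt - 1 / sample_rate_hz) > 1e-9))
      stop("t must be strictly increasing with spacing 1/sample_rate_hz",
           call. = FALSE)
  }
  if (any(pupil_left_mm[valid_left] <= 0, na.rm = TRUE) ||
      any(pupil_right_mm[valid_right] <= 0, na.rm = TRUE))
    stop("pupil diameters must be > 0 wherever valid", call. = FALSE)
  structure(list(
    subject_id = as.character(subject_id), group = group, task = task,
    sample_rate_hz = sample_rate_hz, t = as.numeric(t),
    gaze_x_deg = as.numeric(gaze_x_deg), gaze_y_deg = as.numeric(gaze_y_deg),
    pupil_left_mm = as.numeric(pupil_left_mm),
    pupil_right_mm = as.numeric(pupil_right_mm),
    valid_left = as.logical(valid_left), valid_right = as.logical(valid_right)
  ), class = "gaze_recording")
}

#' @export
print.gaze_recording <- function(x, ...) {
  cat(sprintf("<gaze_recording> %s [%s] %s: %d samples @ %g Hz (%.1f s), %.1f%% valid\n",
              x$subject_id, x$group, x$task, length(x$t), x$sample_rate_hz,
              length(x$t) / x$sample_rate_hz,
              100 * mean(x$valid_left & x$valid_right)))
  invisible(x)
}

# ---- file interchange (CSV) -------------------------------------------------

#' Write / read a stimulus events file
#'
#' One row per trial: subject_id, task, index, side, fixation_onset_s,
#' stimulus_onset_s, stimulus_offset_s, rest_end_s, target_eccentricity_deg.
#'
#' @param schedule A `stimulus_schedule`.
#' @param subject_id Subject identifier stored in the file.
#' @param path Output CSV path.
#' @return `write_events` returns `path` invisibly; `read_events` returns a
#'   `stimulus_schedule`.
#' @export
write_events <- function(schedule, subject_id, path) {
  stopifnot(inherits(schedule, "stimulus_schedule"))
  out <- data.table::data.table(
    subject_id = subject_id, task = attr(schedule, "task"),
    index = schedule$index, side = schedule$side,
    fixation_onset_s = schedule$fixation_onset_s,
    stimulus_onset_s = schedule$stimulus_onset_s,
    stimulus_offset_s = schedule$stimulus_offset_s,
    rest_end_s = schedule$rest_end_s,
    target_eccentricity_deg = schedule$target_eccentricity_deg
  )
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  x <- data.table::fread(path, data.table = FALSE)
  task <- unique(x$task)
  stopifnot(length(task) == 1L)
  sch <- x[order(x$index),
           c("index", "side", "fixation_onset_s", "stimulus_onset_s",
             "stimulus_offset_s", "rest_end_s", "target_eccentricity_deg")]
  rownames(sch) <- NULL
  sch$index <- as.integer(sch$index)
  attr(sch, "task") <- task
  class(sch) <- c("stimulus_schedule", "data.frame")
  validate_schedule(sch)
}

#' Write / read a gaze recording file
#'
#' One row per sample: t, gaze_x_deg, gaze_y_deg, pupil_left_mm,
#' pupil_right_mm, valid_left, valid_right. Subject metadata travels in
#' companion columns so a directory of recordings is self-describing.
#'
#' @param rec A `gaze_recording`.
#' @param path Output CSV path.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns a `gaze_recording`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "gaze_recording"))
  out <- data.table::data.table(
    subject_id = rec$subject_id, group = rec$group, task = rec$task,
    sample_rate_hz = rec$sample_rate_hz,
    t = rec$t, gaze_x_deg = rec$gaze_x_deg, gaze_y_deg = rec$gaze_y_deg,
    pupil_left_mm = rec$pupil_left_mm, pupil_right_mm = rec$pupil_right_mm,
    valid_left = rec$valid_left, valid_right = rec$valid_right
  )
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  x <- data.table::fread(path, data.table = FALSE)
  gaze_recording(
    subject_id = x$subject_id[1], group = x$group[1], task = x$task[1],
    sample_rate_hz = x$sample_rate_hz[1], t = x$t,
    gaze_x_deg = x$gaze_x_deg, gaze_y_deg = x$gaze_y_deg,
    pupil_left_mm = x$pupil_left_mm, pupil_right_mm = x$pupil_right_mm,
    valid_left = x$valid_left, valid_right = x$valid_right
  )
}

# Seed hygiene: temporarily set the RNG, restoring the caller's state.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
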