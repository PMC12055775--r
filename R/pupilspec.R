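# Frequency-domain pupil features: amplitude spectra on a 0.1 Hz grid up to
# a 19 Hz cutoff, band-labelled low/medium/high, averaged over consecutive
# 10 s rectangular windows of the task recording.

SPEC_DF_HZ <- 0.1
SPEC_CUTOFF_HZ <- 19.0
SPEC_WINDOW_S <- 10

#' Frequency grid of the pupil spectrum
#' @return Numeric vector 0.0, 0.1, ..., 19.0 Hz (191 bins).
#' @export
spectrum_freqs <- function() seq(0, SPEC_CUTOFF_HZ, by = SPEC_DF_HZ)

#' Assign a frequency to its band
#'
#' Bands follow the published convention low 0-6 Hz, medium 7-12 Hz, high
#' 13-19 Hz; the half-integer boundaries 6.95 and 12.95 Hz close the
#' unassigned 6-7 and 12-13 Hz gaps so every 0.1 Hz bin has exactly one band.
#'
#' @param frequency_hz Numeric vector in the range 0-19 Hz.
#' @return Character vector: `"low"`, `"medium"`, or `"high"`.
#' @examples
#' assign_band(c(2.1, 11.8, 17.4))
#' @export
assign_band <- function(frequency_hz) {
  if (any(frequency_hz < 0 | frequency_hz > SPEC_CUTOFF_HZ))
    stop("frequency out of range [0, 19] Hz", call. = FALSE)
  ifelse(frequency_hz < 6.95, "low",
         ifelse(frequency_hz < 12.95, "medium", "high"))
}

#' Amplitude spectrum of a pupil trace segment
#'
#' Linear-detrends the segment, applies a rectangular window, and evaluates
#' the amplitude spectrum `2/N * |DFT|` on the 0.1 Hz grid up to 19 Hz.
#' Segments that are not an exact multiple of 10 s are zero-padded to the
#' next multiple (normalisation stays `2/N` with N the true sample count;
#' off-multiple segments therefore leak and are best avoided upstream).
#'
#' @param x Numeric pupil-diameter segment, mm (artifact-repaired).
#' @param sample_rate Sampling rate, Hz (must be >= 2 x cutoff).
#' @param df_hz Grid spacing, Hz. Default 0.1.
#' @param cutoff_hz Highest retained frequency, Hz. Default 19.
#' @return A `pupil_spectrum` data.frame: `frequency_hz`, `amplitude`, `band`.
#' @examples
#' fs <- 120; t <- seq(0, 10 - 1/fs, by = 1/fs)
#' sp <- compute_spectrum(3.5 + 0.4 * sin(2 * pi * 2.1 * t), fs)
#' sp$amplitude[sp$frequency_hz == 2.1]  # ~0.4
#' @export
compute_spectrum <- function(x, sample_rate, df_hz = SPEC_DF_HZ,
                             cutoff_hz = SPEC_CUTOFF_HZ) {
  n <- length(x)
  if (n < 2 * sample_rate)
    stop("segment shorter than 2 s", call. = FALSE)
  if (sample_rate < 2 * cutoff_hz)
    stop("sampling below twice the cutoff frequency", call. = FALSE)
  # remove linear trend (slow diameter drift otherwise dominates near 0 Hz)
  i <- seq_len(n)
  fit <- stats::lm.fit(cbind(1, i), x)
  xd <- fit$residuals
  nwin <- round(sample_rate / df_hz)            # samples per native window
  m <- as.integer(nwin * ceiling(n / nwin))     # zero-padded length
  X <- fft(c(xd, numeric(m - n)))
  freqs <- seq(0, cutoff_hz, by = df_hz)
  idx <- round(freqs * m / sample_rate) + 1L
  amp <- 2 / n * Mod(X[idx])
  out <- data.frame(frequency_hz = freqs, amplitude = amp,
                    band = assign_band(freqs), stringsAsFactors = FALSE)
  class(out) <- c("pupil_spectrum", "data.frame")
  out
}

#' Per-eye frequency features for one task recording
#'
#' Drops samples belonging to excluded trials, splits the remaining trace
#' into consecutive complete 10 s windows, computes the amplitude spectrum
#' per window, and averages bin-wise per eye.
#'
#' @param clean A `clean_recording`.
#' @param schedule Trial schedule (defaults to the one attached by
#'   preprocessing).
#' @return Data.frame of `frequency_feature` rows: `subject_id`, `group`,
#'   `task`, `eye`, `frequency_hz`, `amplitude`, `band` (191 bins per eye).
#' @export
subject_features <- function(clean, schedule = clean$schedule) {
  stopifnot(inherits(clean, "clean_recording"))
  fs <- clean$sample_rate_hz
  keep <- rep(TRUE, length(clean$t))
  excl <- clean$excluded_trials
  if (!is.null(excl) && nrow(excl)) {
    for (k in excl$trial_index) {
      row <- schedule[schedule$index == k, ]
      keep[clean$t >= row$fixation_onset_s & clean$t < row$rest_end_s] <- FALSE
    }
  }
  nwin_len <- as.integer(round(SPEC_WINDOW_S * fs))
  res <- lapply(c("left", "right"), function(eye) {
    p <- (if (eye == "left") clean$pupil_left_mm else clean$pupil_right_mm)[keep]
    nw <- length(p) %/% nwin_len
    if (nw < 1L)
      stop("fewer than one complete ", SPEC_WINDOW_S, " s window after exclusions",
           call. = FALSE)
    acc <- 0
    for (w in seq_len(nw)) {
      seg <- p[((w - 1L) * nwin_len + 1L):(w * nwin_len)]
      acc <- acc + compute_spectrum(seg, fs)$amplitude
    }
    data.frame(subject_id = clean$subject_id, group = clean$group,
               task = clean$task, eye = eye,
               frequency_hz = spectrum_freqs(), amplitude = acc / nw,
               band = assign_band(spectrum_freqs()),
               n_windows = nw, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
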