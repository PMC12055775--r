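# End-to-end orchestration: simulate/load -> preprocess -> saccadic scoring
# -> pupil spectra -> group statistics -> classifier evaluation -> report
# files. Also the feature-extraction glue shared by tests and scripts.

#' Extract summaries and frequency features for a whole cohort
#'
#' Preprocesses every recording, scores both tasks, and computes per-eye
#' frequency features.
#'
#' @param cohort A `cohort` from [simulate_cohort()], or a compatible list
#'   with `subjects`, `recordings`, `schedules`.
#' @param tasks Tasks to analyze. Default both.
#' @param max_interp_ms,landing_tol_deg,stability_ms Analysis parameters
#'   forwarded to preprocessing and scoring.
#' @param what `"all"` (default) or `"features"` to skip saccadic scoring
#'   (e.g. for spectra-only analyses).
#' @return List with `summaries` (one row per subject: 14 saccadic
#'   parameters), `features` (stacked frequency features), and `scores`
#'   (per-trial scores, long).
#' @export
extract_cohort_features <- function(cohort, tasks = task_types(),
                                    max_interp_ms = 75, landing_tol_deg = 2,
                                    stability_ms = 100,
                                    what = c("all", "features")) {
  what <- match.arg(what)
  summaries <- list(); features <- list(); scores <- list()
  for (i in seq_len(nrow(cohort$subjects))) {
    id <- cohort$subjects$subject_id[i]
    grp <- cohort$subjects$group[i]
    per_task <- list()
    for (task in tasks) {
      rec <- cohort$recordings[[id]][[task]]
      sch <- cohort$schedules[[id]][[task]]
      clean <- preprocess_recording(rec, sch, max_interp_ms = max_interp_ms)
      if (what == "all") {
        sc <- score_trials(clean, landing_tol_deg = landing_tol_deg,
                           stability_ms = stability_ms)
        sc$subject_id <- id; sc$group <- grp
        per_task[[task]] <- sc
        scores[[paste(id, task)]] <- sc
      }
      features[[paste(id, task)]] <- subject_features(clean)
    }
    if (what == "all" && all(task_types() %in% tasks))
      summaries[[id]] <- summarize_subject(per_task$pro_saccade,
                                           per_task$anti_saccade,
                                           subject_id = id, group = grp)
  }
  list(summaries = if (length(summaries)) do.call(rbind, summaries) else NULL,
       features = do.call(rbind, features),
       scores = do.call(rbind, scores))
}

#' Run the full analysis pipeline
#'
#' Simulates (or accepts) a cohort, runs preprocessing, saccadic scoring,
#' spectral feature extraction, group statistics with band counting, and the
#' six-model classifier evaluation; writes CSV tables, figures, and a JSON
#' run log to `out_dir`.
#'
#' @param config A `cohort_config` (used when `cohort` is NULL).
#' @param cohort Optional pre-built `cohort` (e.g. loaded from files).
#' @param out_dir Output directory; created if missing. NULL skips writing.
#' @param tasks Tasks to analyze.
#' @param folds,repeats,ntree Classifier evaluation parameters.
#' @param alpha Significance level.
#' @param make_plots Write PNG figures. Default TRUE when `out_dir` is set.
#' @return Report bundle: list with `summaries`, `features`, `tables`
#'   (saccadic, frequency, band_counts), `classifiers` (six reports), and
#'   `log`.
#' @export
run_pipeline <- function(config = cohort_config(), cohort = NULL,
                         out_dir = NULL, tasks = task_types(),
                         folds = 5L, repeats = 10L, ntree = 500L,
                         alpha = 0.05, make_plots = !is.null(out_dir)) {
  if (is.null(cohort)) cohort <- simulate_cohort(config)
  ext <- extract_cohort_features(cohort, tasks = tasks)
  both <- all(task_types() %in% tasks)

  tables <- list(
    frequency = compare_frequency_features(ext$features, alpha))
  tables$band_counts <- count_significant(tables$frequency)
  if (both) tables$saccadic <- compare_saccade_parameters(ext$summaries, alpha)

  classifiers <- NULL
  if (both) {
    eval_seed <- (cohort$config$seed %% 100000L) + 17L
    classifiers <- evaluate_feature_sets(ext$summaries, ext$features,
                                         folds = folds, repeats = repeats,
                                         ntree = ntree, seed = eval_seed)
  }

  log <- list(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    seed = cohort$config$seed,
    n_pd = cohort$config$n_pd, n_control = cohort$config$n_control,
    sample_rate_hz = cohort$config$sample_rate_hz,
    eccentricity_deg = cohort$config$eccentricity_deg,
    tasks = tasks, alpha = alpha,
    cv = sprintf("stratified %d-fold x %d repeats", folds, repeats),
    ntree = ntree)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (both)
      data.table::fwrite(ext$summaries, file.path(out_dir, "subject_summaries.csv"))
    data.table::fwrite(ext$features, file.path(out_dir, "frequency_features.csv"))
    data.table::fwrite(tables$frequency, file.path(out_dir, "frequency_comparisons.csv"))
    data.table::fwrite(as.data.frame(tables$band_counts),
                       file.path(out_dir, "band_counts.csv"))
    if (both) {
      data.table::fwrite(tables$saccadic, file.path(out_dir, "saccadic_comparisons.csv"))
      data.table::fwrite(classifiers$table, file.path(out_dir, "classifier_reports.csv"))
    }
    jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    if (make_plots) {
      grDevices::png(file.path(out_dir, "pupil_trajectories.png"), 900, 500)
      plot_pupil_trajectories(cohort)
      grDevices::dev.off()
      grDevices::png(file.path(out_dir, "amplitude_spectra.png"), 900, 600)
      plot_amplitude_spectra(ext$features)
      grDevices::dev.off()
    }
  }
  invisible(list(summaries = ext$summaries, features = ext$features,
                 tables = tables, classifiers = classifiers, log = log))
}

#' Write / load a cohort as protocol-format CSV files
#'
#' `write_cohort` stores one recording CSV and one events CSV per subject and
#' task under `dir`; `load_cohort` rebuilds a `cohort` object from such a
#' directory (generating-truth metadata is not persisted).
#'
#' @param cohort A `cohort`.
#' @param dir Directory (created if missing).
#' @return `write_cohort` returns `dir` invisibly; `load_cohort` a `cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort$recordings)) for (task in names(cohort$recordings[[id]])) {
    write_recording(cohort$recordings[[id]][[task]],
                    file.path(dir, sprintf("%s_%s_recording.csv", id, task)))
    write_events(cohort$schedules[[id]][[task]], id,
                 file.path(dir, sprintf("%s_%s_events.csv", id, task)))
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
load_cohort <- function(dir) {
  files <- list.files(dir, pattern = "_recording\\.csv$", full.names = TRUE)
  if (!length(files)) stop("no *_recording.csv files in ", dir, call. = FALSE)
  recordings <- list(); schedules <- list(); subjects <- list()
  for (f in files) {
    rec <- read_recording(f)
    ef <- sub("_recording\\.csv$", "_events.csv", f)
    if (!file.exists(ef)) stop("missing events file ", ef, call. = FALSE)
    sch <- read_events(ef)
    recordings[[rec$subject_id]][[rec$task]] <- rec
    schedules[[rec$subject_id]][[rec$task]] <- sch
    subjects[[rec$subject_id]] <- data.frame(
      subject_id = rec$subject_id, group = rec$group, seed = NA_integer_,
      stringsAsFactors = FALSE)
  }
  fs <- recordings[[1]][[1]]$sample_rate_hz
  structure(list(subjects = do.call(rbind, unname(subjects)),
                 recordings = recordings, schedules = schedules, truth = NULL,
                 config = cohort_config(
                   n_pd = max(1L, sum(sapply(subjects, function(s) s$group == "PD"))),
                   n_control = max(1L, sum(sapply(subjects, function(s) s$group == "control"))),
                   sample_rate_hz = fs)),
            class = "cohort")
}

#' Plot trial-locked mean pupil trajectories per group
#'
#' @param cohort A `cohort`.
#' @param task Task to display.
#' @param eye `"left"` or `"right"`.
#' @return Invisibly, the matrix of group mean traces.
#' @export
plot_pupil_trajectories <- function(cohort, task = "pro_saccade", eye = "left") {
  fs <- cohort$config$sample_rate_hz
  win <- as.integer(TRIAL_TOTAL_S * fs)
  grp_mean <- function(group) {
    ids <- cohort$subjects$subject_id[cohort$subjects$group == group]
    acc <- numeric(win); nacc <- 0L
    for (id in ids) {
      rec <- cohort$recordings[[id]][[task]]
      sch <- cohort$schedules[[id]][[task]]
      p <- if (eye == "left") rec$pupil_left_mm else rec$pupil_right_mm
      ok <- if (eye == "left") rec$valid_left else rec$valid_right
      for (k in seq_len(nrow(sch))) {
        i0 <- as.integer(round(sch$fixation_onset_s[k] * fs)) + 1L
        idx <- i0:(i0 + win - 1L)
        if (max(idx) > length(p) || !all(ok[idx])) next
        acc <- acc + p[idx]; nacc <- nacc + 1L
      }
    }
    acc / nacc
  }
  tt <- (seq_len(win) - 1) / fs
  pd <- grp_mean("PD"); hc <- grp_mean("control")
  graphics::plot(tt, hc, type = "l", col = "steelblue", lwd = 2,
                 xlab = "time in trial (s)", ylab = "pupil diameter (mm)",
                 main = sprintf("Trial-locked mean pupil diameter (%s, %s eye)",
                                task, eye),
                 ylim = range(c(pd, hc)))
  graphics::lines(tt, pd, col = "firebrick", lwd = 2)
  graphics::abline(v = c(TRIAL_FIXATION_S, TRIAL_FIXATION_S + TRIAL_STIMULUS_S),
                   lty = 3)
  graphics::legend("bottomleft", c("control", "PD"),
                   col = c("steelblue", "firebrick"), lwd = 2, bty = "n")
  invisible(cbind(t = tt, PD = pd, control = hc))
}

#' Plot group-average amplitude spectra
#'
#' @param features Stacked frequency features.
#' @return Invisibly NULL.
#' @export
plot_amplitude_spectra <- function(features) {
  tasks <- unique(features$task)
  graphics::par(mfrow = c(length(tasks), 2), mar = c(4, 4, 2, 1))
  for (task in tasks) for (eye in c("left", "right")) {
    sub <- features[features$task == task & features$eye == eye, ]
    agg <- function(group) {
      s <- sub[sub$group == group, ]
      tapply(s$amplitude, s$frequency_hz, mean)
    }
    pd <- agg("PD"); hc <- agg("control")
    f <- as.numeric(names(pd))
    graphics::plot(f, hc, type = "l", col = "steelblue", lwd = 1.5,
                   xlab = "frequency (Hz)", ylab = "amplitude (mm)",
                   main = sprintf("%s, %s eye", task, eye),
                   ylim = range(c(pd, hc)))
    graphics::lines(f, pd, col = "firebrick", lwd = 1.5)
    graphics::abline(v = c(6.95, 12.95), lty = 3)
  }
  graphics::par(mfrow = c(1, 1))
  invisible(NULL)
}
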