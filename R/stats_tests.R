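# Two-group comparison machinery: Shapiro-Wilk-gated pooled t vs
# Mann-Whitney U, per-frequency significance, band-wise counting.
# No multiple-testing correction across frequency bins: the published
# analysis reports uncorrected alpha = 0.05 significance per bin, and the
# band counts are defined under that policy.

#' Choose the two-group test via a Shapiro-Wilk normality gate
#'
#' Pooled t-test when the Shapiro-Wilk p-value is >= 0.05 in both groups,
#' Mann-Whitney U otherwise. Degenerate (constant) samples, for which
#' Shapiro-Wilk is undefined, fall through to the nonparametric branch.
#'
#' @param sample_a,sample_b Numeric vectors, each of length >= 3.
#' @param alpha Gate level for the normality test. Default 0.05.
#' @return `"pooled_t"` or `"mann_whitney"`.
#' @export
choose_test <- function(sample_a, sample_b, alpha = 0.05) {
  if (length(sample_a) < 3L || length(sample_b) < 3L)
    stop("each sample needs n >= 3", call. = FALSE)
  sw_ok <- function(x) {
    if (length(unique(x)) < 3L) return(FALSE)   # degenerate -> nonparametric
    p <- tryCatch(shapiro.test(x)$p.value, error = function(e) NA_real_)
    !is.na(p) && p >= alpha
  }
  if (sw_ok(sample_a) && sw_ok(sample_b)) "pooled_t" else "mann_whitney"
}

#' Pooled two-sample t statistic from summary statistics
#'
#' Classical equal-variance t with `df = n_a + n_b - 2`, computable directly
#' from printed group means/SDs -- the verification surface for published
#' summary tables.
#'
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b Group summaries.
#' @return List with `t`, `df`, `p_value` (two-sided). Zero pooled variance
#'   with unequal means yields signed infinity.
#' @examples
#' t_from_summary(206.5, 107.1, 43, 279.5, 105.6, 25)$t  # ~ -2.72
#' @export
t_from_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  stopifnot(n_a >= 2, n_b >= 2, sd_a >= 0, sd_b >= 0)
  df <- n_a + n_b - 2
  sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / df
  se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
  tstat <- if (se == 0) {
    if (mean_a == mean_b) 0 else sign(mean_a - mean_b) * Inf
  } else (mean_a - mean_b) / se
  list(t = tstat, df = df,
       p_value = 2 * stats::pt(-abs(tstat), df))
}

#' Compare one feature between groups
#'
#' Runs the gated test from [choose_test()] and records the statistic,
#' p-value, group summaries, and the significance flag at `alpha`.
#'
#' @param values_pd,values_control Numeric vectors (NAs dropped).
#' @param alpha Significance level. Default 0.05.
#' @param feature_id Identifier carried into the result.
#' @return One-row data.frame (`group_comparison`): `feature_id`,
#'   `test_used`, `statistic`, `p_value`, `mean_pd`, `sd_pd`, `mean_control`,
#'   `sd_control`, `significant`.
#' @export
compare_feature <- function(values_pd, values_control, alpha = 0.05,
                            feature_id = NA_character_) {
  a <- values_pd[!is.na(values_pd)]
  b <- values_control[!is.na(values_control)]
  test <- choose_test(a, b, alpha = 0.05)
  if (test == "pooled_t") {
    ht <- t.test(a, b, var.equal = TRUE)
    statistic <- unname(ht$statistic); p <- ht$p.value
  } else {
    ht <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
    statistic <- unname(ht$statistic); p <- ht$p.value
  }
  if (is.na(p)) p <- 1  # identical constant samples
  data.frame(feature_id = feature_id, test_used = test, statistic = statistic,
             p_value = p, mean_pd = mean(a), sd_pd = sd(a),
             mean_control = mean(b), sd_control = sd(b),
             significant = p < alpha, stringsAsFactors = FALSE)
}

# Fast internal gated test: same decisions as compare_feature (Shapiro-Wilk
# gate, pooled t vs normal-approximation Mann-Whitney with continuity
# correction) without htest-object overhead. Returns c(p_value, is_t).
# Equivalence with the canonical path is asserted in the test suite.
gated_pvalue <- function(a, b, alpha = 0.05) {
  sw_ok <- function(x) {
    if (length(unique(x)) < 3L) return(FALSE)
    p <- tryCatch(shapiro.test(x)$p.value, error = function(e) NA_real_)
    !is.na(p) && p >= alpha
  }
  n1 <- length(a); n2 <- length(b)
  if (sw_ok(a) && sw_ok(b)) {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    if (se == 0) return(c(1, 1))
    tstat <- (mean(a) - mean(b)) / se
    c(2 * stats::pt(-abs(tstat), df), 1)
  } else {
    r <- rank(c(a, b))
    W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    nt <- n1 + n2
    ties <- table(r)
    sig2 <- n1 * n2 / 12 * ((nt + 1) - sum(ties^3 - ties) / (nt * (nt - 1)))
    if (sig2 <= 0) return(c(1, 0))
    z <- (abs(W - mu) - 0.5) / sqrt(sig2)
    c(2 * pnorm(-z), 0)
  }
}

#' Chi-squared comparison of group counts
#'
#' For categorical demographics (e.g. sex ratios): 2x2 chi-squared test.
#'
#' @param k_pd,n_pd Events and totals in the PD group.
#' @param k_control,n_control Events and totals in the control group.
#' @param alpha Significance level.
#' @return One-row data.frame with `test_used = "chi_squared"`.
#' @export
compare_counts <- function(k_pd, n_pd, k_control, n_control, alpha = 0.05) {
  m <- matrix(c(k_pd, n_pd - k_pd, k_control, n_control - k_control), 2)
  ht <- suppressWarnings(chisq.test(m))
  data.frame(feature_id = NA_character_, test_used = "chi_squared",
             statistic = unname(ht$statistic), p_value = ht$p.value,
             mean_pd = 100 * k_pd / n_pd, sd_pd = NA_real_,
             mean_control = 100 * k_control / n_control, sd_control = NA_real_,
             significant = ht$p.value < alpha, stringsAsFactors = FALSE)
}

#' Count significant frequencies per band
#'
#' Tallies significant bins per (task, eye, band) and adds both-eye totals
#' per (task, band).
#'
#' @param results Data.frame of per-bin comparison results with columns
#'   `task`, `eye`, `frequency_hz`, `significant`.
#' @return A `band_counts` data.frame: `task`, `eye` (including
#'   `"both"` totals), `low`, `medium`, `high`.
#' @export
count_significant <- function(results) {
  need <- c("task", "eye", "frequency_hz", "significant")
  stopifnot(all(need %in% names(results)))
  key <- paste(results$task, results$eye, results$frequency_hz)
  if (anyDuplicated(key))
    stop("duplicate (task, eye, frequency) keys in results", call. = FALSE)
  results$band <- assign_band(results$frequency_hz)
  out <- list()
  for (task in unique(results$task)) {
    sub <- results[results$task == task, ]
    rows <- lapply(c("left", "right"), function(eye) {
      s <- sub[sub$eye == eye, ]
      data.frame(task = task, eye = eye,
                 low = sum(s$significant[s$band == "low"]),
                 medium = sum(s$significant[s$band == "medium"]),
                 high = sum(s$significant[s$band == "high"]),
                 stringsAsFactors = FALSE)
    })
    rows <- do.call(rbind, rows)
    both <- data.frame(task = task, eye = "both",
                       low = sum(rows$low), medium = sum(rows$medium),
                       high = sum(rows$high), stringsAsFactors = FALSE)
    out[[task]] <- rbind(rows, both)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("band_counts", "data.frame")
  out
}

#' Compare all saccadic parameters between groups
#'
#' @param summaries Data.frame of subject rows from [summarize_subject()]
#'   including a `group` column.
#' @param alpha Significance level.
#' @return Data.frame with one comparison row per saccadic parameter
#'   (report analogue of the published saccadic comparison table).
#' @export
compare_saccade_parameters <- function(summaries, alpha = 0.05) {
  pd <- summaries[summaries$group == "PD", ]
  hc <- summaries[summaries$group == "control", ]
  res <- lapply(saccade_parameter_names(), function(p)
    compare_feature(pd[[p]], hc[[p]], alpha, feature_id = p))
  do.call(rbind, res)
}

#' Compare all frequency features between groups
#'
#' @param features Stacked output of [subject_features()] across subjects.
#' @param alpha Significance level.
#' @return Data.frame with one row per (task, eye, frequency bin):
#'   comparison result plus `task`, `eye`, `frequency_hz`, `band`.
#' @export
compare_frequency_features <- function(features, alpha = 0.05) {
  out <- list()
  for (task in unique(features$task)) for (eye in c("left", "right")) {
    sub <- features[features$task == task & features$eye == eye, ]
    for (f in unique(sub$frequency_hz)) {
      s <- sub[sub$frequency_hz == f, ]
      r <- compare_feature(s$amplitude[s$group == "PD"],
                           s$amplitude[s$group == "control"], alpha,
                           feature_id = sprintf("%s_%s_f%05.1f", task, eye, f))
      r$task <- task; r$eye <- eye; r$frequency_hz <- f
      r$band <- assign_band(f)
      out[[length(out) + 1L]] <- r
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Report-style summary tables
#'
#' Builds the two report structures of the analysis: per-parameter group
#' means +/- SD with test results (saccadic table analogue) and
#' per-frequency average amplitudes per eye/task with significance markers
#' (frequency-amplitude table analogue).
#'
#' @param summaries Subject saccadic summaries with `group`.
#' @param features Stacked frequency features.
#' @param alpha Significance level.
#' @return List with `saccadic` and `frequency` data.frames and `band_counts`.
#' @export
summary_tables <- function(summaries, features, alpha = 0.05) {
  sac <- compare_saccade_parameters(summaries, alpha)
  frq <- compare_frequency_features(features, alpha)
  list(saccadic = sac, frequency = frq,
       band_counts = count_significant(frq))
}
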