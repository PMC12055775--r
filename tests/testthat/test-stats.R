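test_that("normality gate routes to the right test", {
  set.seed(10)
  a <- rnorm(40); b <- rnorm(40)
  expect_identical(choose_test(a, b), "pooled_t")
  skewed <- rexp(40)
  expect_identical(choose_test(a, skewed), "mann_whitney")
  expect_identical(choose_test(skewed, b), "mann_whitney")
  expect_identical(choose_test(rep(1, 10), b), "mann_whitney")  # degenerate
  expect_error(choose_test(1:2, b), "n >= 3")
})

test_that("pooled t from summaries reproduces published statistics", {
  expect_equal(t_from_summary(206.5, 107.1, 43, 279.5, 105.6, 25)$t,
               -2.72, tolerance = 0.005)
  expect_equal(t_from_summary(154.8, 81.3, 43, 184.5, 101.1, 25)$t,
               -1.33, tolerance = 0.005)
  expect_equal(t_from_summary(5, 1, 10, 5, 1, 10)$t, 0)
  expect_identical(t_from_summary(2, 0, 5, 1, 0, 5)$t, Inf)
})

test_that("t_from_summary agrees with t.test on raw data", {
  set.seed(2)
  for (i in 1:20) {
    a <- rnorm(sample(5:40, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(5:40, 1), mean = runif(1, -1, 1))
    ref <- t.test(a, b, var.equal = TRUE)
    got <- t_from_summary(mean(a), sd(a), length(a), mean(b), sd(b), length(b))
    expect_equal(got$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("compare_feature flags forced separations and not identical data", {
  set.seed(3)
  a <- rnorm(30)
  r0 <- compare_feature(a, a)
  expect_false(r0$significant)
  expect_lt(abs(r0$statistic), 1e-8)
  r1 <- compare_feature(rnorm(30), rnorm(30) + 5)
  expect_true(r1$significant)
})

test_that("Mann-Whitney branch matches the exhaustive permutation oracle", {
  # small samples, no ties: the rank-sum permutation null is enumerable
  set.seed(8)
  for (rep in 1:5) {
    a <- round(runif(6, 0, 100), 3); b <- round(runif(5, 0, 100), 3)
    pooled <- c(a, b); n1 <- length(a); n <- length(pooled)
    W_obs <- sum(rank(pooled)[1:n1]) - n1 * (n1 + 1) / 2
    combs <- utils::combn(n, n1)
    W_null <- apply(combs, 2, function(ix)
      sum(rank(pooled)[ix]) - n1 * (n1 + 1) / 2)
    mu <- n1 * (n - n1) / 2
    p_perm <- mean(abs(W_null - mu) >= abs(W_obs - mu))
    p_exact <- wilcox.test(a, b, exact = TRUE)$p.value
    expect_equal(p_exact, p_perm, tolerance = 1e-12)
  }
})

test_that("fast gated p-values equal the canonical compare_feature path", {
  set.seed(12)
  for (i in 1:30) {
    a <- if (i %% 2) rnorm(25) else rexp(25)
    b <- rnorm(18)
    ref <- compare_feature(a, b)
    fast <- oculopd:::gated_pvalue(a, b)
    expect_equal(fast[1], ref$p_value, tolerance = 1e-10)
    expect_identical(unname(fast[2] == 1), ref$test_used == "pooled_t")
  }
})

test_that("band counting reproduces the published both-eye totals", {
  flags <- expand.grid(task = c("pro_saccade", "anti_saccade"),
                       eye = c("left", "right"),
                       frequency_hz = spectrum_freqs(),
                       stringsAsFactors = FALSE)
  flags$band <- assign_band(flags$frequency_hz)
  # per-eye published counts: pro L 11/4/10, R 12/5/6; anti L 4/11/18, R 6/18/25
  per_eye <- list(
    pro_saccade = list(left = c(11, 4, 10), right = c(12, 5, 6)),
    anti_saccade = list(left = c(4, 11, 18), right = c(6, 18, 25)))
  flags$significant <- FALSE
  for (task in names(per_eye)) for (eye in names(per_eye[[task]])) {
    k <- per_eye[[task]][[eye]]
    for (bi in seq_along(c("low", "medium", "high"))) {
      band <- c("low", "medium", "high")[bi]
      idx <- which(flags$task == task & flags$eye == eye & flags$band == band)
      flags$significant[idx[seq_len(k[bi])]] <- TRUE
    }
  }
  counts <- count_significant(flags)
  pro_both <- counts[counts$task == "pro_saccade" & counts$eye == "both", ]
  anti_both <- counts[counts$task == "anti_saccade" & counts$eye == "both", ]
  expect_equal(unlist(pro_both[c("low", "medium", "high")], use.names = FALSE),
               c(23, 9, 16))
  expect_equal(unlist(anti_both[c("low", "medium", "high")], use.names = FALSE),
               c(10, 29, 43))

  # order invariance and degenerate cases
  shuffled <- flags[sample(nrow(flags)), ]
  expect_equal(count_significant(shuffled), counts)
  flags$significant <- FALSE
  z <- count_significant(flags)
  expect_true(all(z[, c("low", "medium", "high")] == 0))
  flags$significant <- TRUE
  sat <- count_significant(flags)
  both <- sat[sat$eye == "both" & sat$task == "pro_saccade", ]
  expect_equal(unlist(both[c("low", "medium", "high")], use.names = FALSE),
               2 * c(70, 60, 61))       # band bin counts per eye: 70/60/61
  expect_error(count_significant(rbind(flags, flags[1, ])), "duplicate")
})

test_that("chi-squared count comparison works on 2x2 tables", {
  r <- compare_counts(14, 43, 14, 25)
  expect_identical(r$test_used, "chi_squared")
  expect_gt(r$p_value, 0.05)
  expect_equal(r$mean_pd, 100 * 14 / 43, tolerance = 1e-9)
})
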