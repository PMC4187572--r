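test_that("screening applies the MVC range and IPAQ cap", {
  expect_true(screen_subject(451, 3844))    # cohort-typical values
  expect_false(screen_subject(150, 3000))   # below the MVC range
  expect_false(screen_subject(451, 10001))  # IPAQ rule
  # boundaries are inside the range ('outside the range' excludes)
  expect_true(screen_subject(200, 10000))
  expect_true(screen_subject(700, 0))
  expect_false(screen_subject(701, 0))
  expect_equal(screen_subject(c(451, 150), c(3844, 3000)), c(TRUE, FALSE))
})

test_that("BP and physiological characteristic values follow the aggregation rules", {
  expect_equal(bp_characteristic(c(120, 110, 114)), 112)
  b <- bp_characteristic(c(999, 110, 114))
  expect_true(b >= 110 && b <= 114)  # reading 1 is discarded
  expect_error(bp_characteristic(c(120, 110)), "3")
  expect_equal(physio_characteristic(c(60, 62, NA, 64)), 62)
})

test_that("KS normality check is calibrated on normal data and powered on exponential data", {
  # normal samples: almost never rejected (parameter estimation makes the
  # classical KS conservative)
  set.seed(55)
  ps <- replicate(100, ks_normality(rnorm(1000))$p)
  expect_gte(mean(ps > 0.05), 0.95)
  # strongly non-normal sample: decisively rejected
  set.seed(56)
  expect_lt(ks_normality(rexp(200))$p, 0.01)
  expect_error(ks_normality(rep(3, 10)), "degenerate")
  expect_error(ks_normality(c(1, 2)), "at least 3")
  # Lilliefors variant rejects at least as readily
  set.seed(57)
  x <- rexp(50)
  expect_lte(ks_normality(x, lilliefors = TRUE)$p, ks_normality(x)$p)
})

test_that("paired comparison matches the hand-computed t statistic", {
  r <- paired_comparison(c(2, 4, 6), c(1, 2, 3))  # differences 1, 2, 3
  expect_equal(r$t, 2 / (1 / sqrt(3)), tolerance = 1e-10)
  expect_equal(r$df, 2)
  expect_equal(r$p, 2 * pt(-2 * sqrt(3), df = 2), tolerance = 1e-10)
  expect_equal(r$p, 0.0742, tolerance = 1e-3)
  # identical vectors: no shift, t = 0, p = 1
  z <- paired_comparison(c(1, 2, 3), c(1, 2, 3))
  expect_equal(z$t, 0); expect_equal(z$p, 1)
  # constant non-zero differences are undefined
  expect_error(paired_comparison(c(2, 3, 4), c(1, 2, 3)), "undefined")
  # two-tailed symmetry: swapping the visits flips t, not p
  a <- rnorm(9); b <- rnorm(9)
  expect_equal(paired_comparison(a, b)$p, paired_comparison(b, a)$p)
  expect_equal(paired_comparison(a, b)$t, -paired_comparison(b, a)$t)
})

test_that("paired test type-I error is calibrated at alpha 0.05", {
  set.seed(99)
  n_rep <- 10000
  x <- matrix(rnorm(9 * n_rep), 9)
  y <- matrix(rnorm(9 * n_rep), 9)
  ps <- vapply(seq_len(n_rep),
               function(i) paired_comparison(x[, i], y[, i])$p, numeric(1))
  expect_true(all(ps >= 0 & ps <= 1))
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.01)
})

test_that("repeated-measures ANOVA matches a brute-force sum-of-squares decomposition", {
  set.seed(7)
  n <- 6; k <- 3
  m <- matrix(rnorm(n * k, mean = rep(c(10, 11, 12.5), each = n)), n, k)
  got <- rm_anova(m)
  # brute force: SS_visit over SS_residual after removing subject + visit means
  grand <- mean(m)
  ss_visit <- n * sum((colMeans(m) - grand)^2)
  resid <- m - outer(rowMeans(m), rep(1, k)) -
    outer(rep(1, n), colMeans(m)) + grand
  ss_res <- sum(resid^2)
  f_brute <- (ss_visit / (k - 1)) / (ss_res / ((k - 1) * (n - 1)))
  expect_equal(got$F, f_brute, tolerance = 1e-10)
  expect_equal(got$df1, k - 1)
  expect_equal(got$df2, (k - 1) * (n - 1))
  expect_equal(got$p, pf(f_brute, k - 1, (k - 1) * (n - 1),
                         lower.tail = FALSE), tolerance = 1e-10)
  # identical columns: F = 0, p = 1
  same <- matrix(rep(rnorm(5), 3), 5, 3)
  z <- rm_anova(same)
  expect_equal(z$F, 0, tolerance = 1e-12)
  expect_equal(z$p, 1, tolerance = 1e-12)
  # shuffling subjects (rows) leaves F unchanged
  got2 <- rm_anova(m[sample(n), ])
  expect_equal(got2$F, got$F, tolerance = 1e-10)
  expect_error(rm_anova(m[, 1, drop = FALSE]), ">= 2")
  m_na <- m; m_na[2, 2] <- NA
  expect_error(rm_anova(m_na), "missing")
})

test_that("for two visits the ANOVA F equals the squared paired t", {
  set.seed(21)
  x <- rnorm(9, 5, 2); y <- rnorm(9, 6, 2)
  f <- rm_anova(cbind(x, y))$F
  t <- paired_comparison(x, y)$t
  expect_equal(f, t^2, tolerance = 1e-10)
  expect_equal(rm_anova(cbind(x, y))$p, paired_comparison(x, y)$p,
               tolerance = 1e-10)
})

test_that("Pearson correlation p-values follow the t transform", {
  expect_lt(abs(pearson_p_from_r(-0.7810, 9) - 0.0130), 5e-4)
  expect_equal(pearson_p_from_r(0, 9), 1)
  expect_equal(pearson_p_from_r(1, 9), 0)
  x <- c(1, 3, 2, 5, 4)
  r <- pearson_with_p(x, x)
  expect_equal(r$r, 1)
  expect_lt(r$p, 1e-10)
  # agreement with the analytic transform on real data
  set.seed(5)
  a <- rnorm(9); b <- rnorm(9)
  got <- pearson_with_p(a, b)
  expect_equal(got$p, pearson_p_from_r(got$r, 9), tolerance = 1e-12)
  expect_error(pearson_with_p(rep(1, 5), rnorm(5)), "zero-variance")
})

test_that("correlate_changes finds a planted correlation and drops unmatched subjects", {
  # construct delta vectors with an exact sample correlation of -0.781
  set.seed(31)
  n <- 9
  x <- scale(rnorm(n))[, 1]
  z <- residuals(lm(rnorm(n) ~ x)); z <- z / sqrt(sum(z^2) / (n - 1))
  r_target <- -0.781
  y <- r_target * x + sqrt(1 - r_target^2) * z
  # metrics: visit-1 values 0, visit-2 values = x (so delta = x)
  metrics <- rbind(
    data.frame(subject = 1:n, visit = 1, workload = 25,
               muscle = "gastrocnemius", metric = "maximal_change",
               value = 0),
    data.frame(subject = 1:n, visit = 2, workload = 25,
               muscle = "gastrocnemius", metric = "maximal_change",
               value = x))
  bp <- rbind(
    data.frame(subject = 1:n, visit = 1, systolic = 0, diastolic = rnorm(n)),
    data.frame(subject = 1:n, visit = 2, systolic = y, diastolic = rnorm(n)))
  out <- correlate_changes(metrics, bp, visit_pairs = list(c(1, 2)))
  sys <- out[out$bp_component == "systolic", ]
  expect_equal(sys$r, -0.781, tolerance = 1e-10)
  expect_lt(abs(sys$p - 0.0130), 5e-4)
  expect_equal(sys$n, 9)
  # a subject missing from one visit is dropped and n reflects it
  metrics2 <- metrics[!(metrics$subject == 9 & metrics$visit == 2), ]
  out2 <- correlate_changes(metrics2, bp, visit_pairs = list(c(1, 2)))
  expect_equal(out2$n[out2$bp_component == "systolic"], 8)
  # identical deltas give r = 1
  bp3 <- bp; bp3$systolic[bp3$visit == 2] <- x
  out3 <- correlate_changes(metrics, bp3, visit_pairs = list(c(1, 2)))
  expect_equal(out3$r[out3$bp_component == "systolic"], 1, tolerance = 1e-12)
})

test_that("visit summaries reproduce injected group parameters on a synthetic cohort", {
  set.seed(77)
  n <- 40
  mu <- c(`1` = 5.4, `2` = 6.0, `3` = 4.3)
  rows <- do.call(rbind, lapply(names(mu), function(v)
    data.frame(subject = 1:n, visit = as.integer(v), workload = 15,
               muscle = "gastrocnemius", metric = "maximal_change",
               value = rnorm(n, mu[v], 1))))
  vs <- visit_summary(rows)
  for (v in 1:3) {
    se <- 1 / sqrt(n)
    expect_lt(abs(vs[[paste0("mean_v", v)]] - mu[as.character(v)]), 3 * se)
    expect_equal(vs[[paste0("sd_v", v)]], 1, tolerance = 0.35)
  }
  # a large real shift is detected by both paired t and RM-ANOVA
  expect_lt(vs$p_2v3, 0.01)
  expect_lt(vs$p_anova, 0.01)
})
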