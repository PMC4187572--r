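#' Subject screening rule
#'
#' A subject is eligible when MVC lies inside 200-700 N (endpoints
#' eligible: exclusion applies only *outside* the range) and the IPAQ
#' physical-activity score does not exceed 10,000 MET-minutes.
#'
#' @param mvc Maximum voluntary contraction in Newtons (vectorised).
#' @param ipaq IPAQ score in MET-minutes (vectorised).
#' @return Logical eligibility flag(s).
#' @export
#' @examples
#' screen_subject(451, 3844)   # TRUE
#' screen_subject(150, 3000)   # FALSE
screen_subject <- function(mvc, ipaq) {
  stopifnot(all(mvc >= 0), all(ipaq >= 0))
  mvc >= 200 & mvc <= 700 & ipaq <= 10000
}

#' Characteristic blood pressure from three readings
#'
#' Three BP measurements are taken at 5 min intervals during supine rest;
#' the characteristic value is the mean of the second and third readings
#' (the first is discarded as an accommodation reading).
#'
#' @param readings Numeric vector of exactly three readings.
#' @return The characteristic value.
#' @export
bp_characteristic <- function(readings) {
  stopifnot(length(readings) == 3, all(is.finite(readings)))
  mean(readings[2:3])
}

#' Characteristic value of a resting physiological recording
#'
#' Physiological traces (oxygen saturation, heart rate, breathing rate,
#' inspired/end-tidal CO2) recorded over the final rest period are
#' summarised by their mean.
#'
#' @param values Numeric recording.
#' @return Mean of the finite values.
#' @export
physio_characteristic <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) == 0) stop("no finite recordings")
  mean(v)
}

#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS test of the sample against a normal distribution with
#' the sample's own mean and SD (the common statistics-package usage).
#' Estimating the parameters from the same sample makes the classical
#' p-value conservative (inflated); `lilliefors = TRUE` applies the
#' Lilliefors correction instead (requires the nortest package).
#'
#' @param x Numeric sample, `n >= 3`, non-degenerate.
#' @param lilliefors Use the Lilliefors-corrected test.
#' @return List with `statistic` and `p`.
#' @export
ks_normality <- function(x, lilliefors = FALSE) {
  x <- x[is.finite(x)]
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) < .Machine$double.eps^0.5)
    stop("degenerate (zero-variance) sample")
  if (lilliefors) {
    if (!requireNamespace("nortest", quietly = TRUE))
      stop("the Lilliefors variant requires the nortest package")
    ht <- nortest::lillie.test(x)
  } else {
    ht <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
  }
  list(statistic = unname(ht$statistic), p = unname(ht$p.value))
}

#' Paired comparison between two visits
#'
#' Classical paired t-test on the within-subject differences with
#' `df = n - 1`, two-tailed. Identical vectors (all differences zero)
#' return `t = 0, p = 1` — no evidence of a shift; constant non-zero
#' differences are an error (the statistic is undefined).
#'
#' @param x,y Matched per-subject values for the two visits; equal
#'   length, `n >= 2`.
#' @return List with `t`, `df`, `p`, `mean_diff`, `n`.
#' @export
#' @examples
#' paired_comparison(c(2, 4, 6), c(1, 2, 3))  # t ~ 3.46, p ~ 0.074
paired_comparison <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  n <- length(d)
  if (stats::sd(d) < .Machine$double.eps^0.5) {
    if (abs(mean(d)) < .Machine$double.eps^0.5)
      return(list(t = 0, df = n - 1, p = 1, mean_diff = 0, n = n))
    stop("zero-variance non-zero differences: t statistic undefined")
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = unname(tt$estimate), n = n)
}

#' One-way repeated-measures ANOVA across visits
#'
#' Within-subject one-way ANOVA on a complete subject-by-visit matrix:
#' the visit effect is tested against the subject-by-visit residual with
#' `df1 = k - 1`, `df2 = (k - 1)(n - 1)`. For `k = 2` the F statistic
#' equals the squared paired t statistic.
#'
#' @param values Numeric matrix, rows = subjects, columns = visits;
#'   complete (no NA), `>= 2` rows and columns.
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
rm_anova <- function(values) {
  values <- as.matrix(values)
  n <- nrow(values); k <- ncol(values)
  if (n < 2 || k < 2) stop("need >= 2 subjects and >= 2 visits")
  if (any(!is.finite(values))) stop("incomplete matrix: missing values")
  df_long <- data.frame(
    value = as.vector(values),
    subject = factor(rep(seq_len(n), times = k)),
    visit = factor(rep(seq_len(k), each = n)))
  # no between-visit variation: F = 0, p = 1 (avoids a 0/0 in the F ratio
  # when the residual SS is also exactly zero, e.g. identical columns)
  grand <- mean(values)
  ss_visit <- n * sum((colMeans(values) - grand)^2)
  ss_total <- sum((values - grand)^2)
  if (ss_visit <= 1e-12 * max(ss_total, 1))
    return(list(F = 0, df1 = k - 1, df2 = (k - 1) * (n - 1), p = 1))
  fit <- stats::aov(value ~ visit + Error(subject), data = df_long)
  tab <- summary(fit)[["Error: Within"]][[1]]
  Fv <- tab["visit", "F value"]
  p <- tab["visit", "Pr(>F)"]
  list(F = unname(Fv), df1 = k - 1, df2 = (k - 1) * (n - 1), p = unname(p))
}

#' Pearson correlation with a two-tailed p-value
#'
#' `p` comes from `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2`
#' degrees of freedom.
#'
#' @param x,y Numeric vectors, `n >= 3`, non-degenerate.
#' @return List with `r`, `p`, `n`.
#' @export
pearson_with_p <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) < .Machine$double.eps^0.5 ||
      stats::sd(y) < .Machine$double.eps^0.5)
    stop("zero-variance input")
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Two-tailed p-value for a given Pearson r and sample size
#'
#' The significance of a reported correlation coefficient:
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)`, two-tailed on `n - 2` df.
#' `|r| = 1` returns `p = 0`.
#'
#' @param r Correlation coefficient in `[-1, 1]`.
#' @param n Number of pairs, `>= 3`.
#' @return Two-tailed p-value.
#' @export
#' @examples
#' pearson_p_from_r(-0.7810, 9)  # ~0.013
pearson_p_from_r <- function(r, n) {
  stopifnot(abs(r) <= 1, n >= 3)
  if (abs(r) == 1) return(0)
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * stats::pt(-abs(t), df = n - 2)
}

#' Correlate between-visit metric changes with blood-pressure changes
#'
#' For every combination of workload, muscle, metric, visit pair and BP
#' component, computes the Pearson correlation (with p) between the
#' per-subject change in the oxygenation metric and the corresponding
#' change in BP. Subjects missing either visit are dropped
#' (complete-case pairing) and the n actually used is reported.
#'
#' @param metrics Data frame with columns `subject`, `visit`, `workload`,
#'   `muscle`, `metric`, `value` (long VisitTable format).
#' @param bp Data frame with columns `subject`, `visit`, `systolic`,
#'   `diastolic`.
#' @param visit_pairs List of length-2 visit vectors; change = second
#'   minus first.
#' @return Data frame with columns workload, metric, muscle,
#'   bp_component, visit_pair, n, r, p.
#' @export
correlate_changes <- function(metrics, bp,
                              visit_pairs = list(c(1, 2), c(2, 3), c(3, 1))) {
  need <- c("subject", "visit", "workload", "muscle", "metric", "value")
  stopifnot(all(need %in% names(metrics)),
            all(c("subject", "visit", "systolic", "diastolic") %in% names(bp)))
  grid <- unique(metrics[, c("workload", "metric", "muscle")])
  rows <- list()
  for (pair in visit_pairs) {
    pair_lab <- paste0(pair[1], "-", pair[2])
    bp1 <- bp[bp$visit == pair[1], ]
    bp2 <- bp[bp$visit == pair[2], ]
    for (g in seq_len(nrow(grid))) {
      sel <- metrics$workload == grid$workload[g] &
        metrics$metric == grid$metric[g] & metrics$muscle == grid$muscle[g]
      m1 <- metrics[sel & metrics$visit == pair[1], c("subject", "value")]
      m2 <- metrics[sel & metrics$visit == pair[2], c("subject", "value")]
      subj <- Reduce(intersect, list(m1$subject, m2$subject,
                                     bp1$subject, bp2$subject))
      for (comp in c("systolic", "diastolic")) {
        if (length(subj) < 3) {
          rows[[length(rows) + 1]] <- data.frame(
            workload = grid$workload[g], metric = grid$metric[g],
            muscle = grid$muscle[g], bp_component = comp,
            visit_pair = pair_lab, n = length(subj),
            r = NA_real_, p = NA_real_)
          next
        }
        dm <- m2$value[match(subj, m2$subject)] -
          m1$value[match(subj, m1$subject)]
        db <- bp2[[comp]][match(subj, bp2$subject)] -
          bp1[[comp]][match(subj, bp1$subject)]
        ct <- pearson_with_p(dm, db)
        rows[[length(rows) + 1]] <- data.frame(
          workload = grid$workload[g], metric = grid$metric[g],
          muscle = grid$muscle[g], bp_component = comp,
          visit_pair = pair_lab, n = ct$n, r = ct$r, p = ct$p)
      }
    }
  }
  do.call(rbind, rows)
}

#' Visit-comparison summary of a metric table
#'
#' Per (workload, metric, muscle): mean and SD per visit, paired t-test
#' p-values for each visit pair, and the one-way repeated-measures ANOVA
#' p across all visits (complete-case subjects). No multiple-testing
#' correction is applied (single pre-defined comparisons at alpha 0.05).
#'
#' @inheritParams correlate_changes
#' @return Data frame, one row per (workload, metric, muscle).
#' @export
visit_summary <- function(metrics,
                          visit_pairs = list(c(1, 2), c(2, 3), c(3, 1))) {
  grid <- unique(metrics[, c("workload", "metric", "muscle")])
  visits <- sort(unique(metrics$visit))
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    sel <- metrics$workload == grid$workload[g] &
      metrics$metric == grid$metric[g] & metrics$muscle == grid$muscle[g]
    sub <- metrics[sel, ]
    wide <- stats::reshape(sub[, c("subject", "visit", "value")],
                           idvar = "subject", timevar = "visit",
                           direction = "wide")
    complete <- wide[stats::complete.cases(wide), ]
    row <- grid[g, ]
    for (v in visits) {
      vals <- sub$value[sub$visit == v]
      row[[paste0("mean_v", v)]] <- mean(vals, na.rm = TRUE)
      row[[paste0("sd_v", v)]] <- stats::sd(vals, na.rm = TRUE)
    }
    for (pair in visit_pairs) {
      x <- complete[[paste0("value.", pair[1])]]
      y <- complete[[paste0("value.", pair[2])]]
      row[[paste0("p_", pair[1], "v", pair[2])]] <-
        if (length(x) >= 2) paired_comparison(x, y)$p else NA_real_
    }
    mat <- as.matrix(complete[, paste0("value.", visits), drop = FALSE])
    row$p_anova <- if (nrow(mat) >= 2 && ncol(mat) >= 2)
      rm_anova(mat)$p else NA_real_
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
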