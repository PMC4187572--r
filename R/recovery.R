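#' Mono-exponential fit of the post-exercise recovery
#'
#' Fits `y(t) = plateau + (peak - plateau) * exp(-t / tau)` to the
#' recovery-phase frames of a cycle-averaged percent-change series, where
#' `t` is time since the end of the exercise block. Nonlinear least
#' squares (Levenberg-Marquardt) with deterministic initialisation:
#' `peak0` = first recovery frame, `plateau0` = mean of the final 15 s of
#' recovery, `tau0` = 30 s, with `tau` bounded to (0.1, 600] s. A fit
#' whose `tau` lands on the upper bound is flagged (`tau_at_bound`); a
#' flat segment is flagged `degenerate` (tau unidentifiable) — flags are
#' honest, metrics are never fabricated from a failed fit.
#'
#' @param cycle_avg Cycle-averaged series (one value per within-cycle
#'   frame, as from [cycle_average()]).
#' @param paradigm An [exercise_paradigm()] object.
#' @param tr Repetition time in seconds.
#' @param tau_bounds Lower/upper bounds for tau in seconds.
#' @return An object of class `exponential_fit`: list with `peak`,
#'   `plateau`, `tau`, `rss`, `converged`, `degenerate`, `tau_at_bound`,
#'   `n_frames`.
#' @export
#' @examples
#' p <- exercise_paradigm()
#' t_rec <- seq(0, 117, by = 3)
#' y <- c(rep(0, 30), 1 + 4 * exp(-t_rec / 40))
#' fit_recovery(y, p, tr = 3)$tau  # ~40
fit_recovery <- function(cycle_avg, paradigm, tr, tau_bounds = c(0.1, 600)) {
  tc <- (seq_along(cycle_avg) - 1) * tr
  rec <- tc >= paradigm$exercise_duration
  t_rec <- tc[rec] - paradigm$exercise_duration
  y <- cycle_avg[rec]
  if (length(y) < 4)
    stop("recovery segment has fewer than 4 frames")
  out <- list(peak = NA_real_, plateau = NA_real_, tau = NA_real_,
              rss = NA_real_, converged = FALSE, degenerate = FALSE,
              tau_at_bound = FALSE, n_frames = length(y))
  if (stats::sd(y) < 1e-12) {
    out$peak <- out$plateau <- y[1]
    out$tau <- NA_real_
    out$rss <- 0
    out$degenerate <- TRUE
    class(out) <- "exponential_fit"
    return(out)
  }
  tail_sel <- t_rec >= max(t_rec) - 15
  start <- list(peak = y[1], plateau = mean(y[tail_sel]), tau = 30)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ plateau + (peak - plateau) * exp(-t_rec / tau),
                      data = data.frame(t_rec = t_rec, y = y),
                      start = start,
                      lower = c(peak = -Inf, plateau = -Inf, tau = tau_bounds[1]),
                      upper = c(peak = Inf, plateau = Inf, tau = tau_bounds[2]),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    class(out) <- "exponential_fit"
    return(out)
  }
  cf <- stats::coef(fit)
  out$peak <- unname(cf["peak"])
  out$plateau <- unname(cf["plateau"])
  out$tau <- unname(cf["tau"])
  out$rss <- sum(stats::resid(fit)^2)
  out$tau_at_bound <- out$tau >= tau_bounds[2] * (1 - 1e-6)
  out$converged <- !out$tau_at_bound
  class(out) <- "exponential_fit"
  out
}

#' Tissue-oxygenation metrics from a cycle-averaged response
#'
#' The two headline metrics: **maximal change** is the peak amplitude of
#' the cycle-averaged percent-change series (maximum over within-cycle
#' frames, first occurrence on ties); **recovery change** is the maximal
#' change minus the fitted model value at the end of the recovery window
#' (the "trough" is taken from the exponential fit, not the raw minimum,
#' since the fit precedes metric extraction; set `raw_trough = TRUE` for
#' the raw-minimum variant). The normalised variant divides the
#' difference by the maximal change; both forms are reported. Fit flags
#' propagate: a degenerate (flat) recovery yields recovery change 0, a
#' non-converged fit yields `NA` recovery metrics.
#'
#' @param cycle_avg Cycle-averaged percent-change series.
#' @param fit An `exponential_fit` from [fit_recovery()].
#' @param paradigm An [exercise_paradigm()] object.
#' @param tr Repetition time in seconds.
#' @param raw_trough Use the raw minimum of the recovery segment instead
#'   of the fitted end-of-recovery value.
#' @return An object of class `oxygenation_metrics`: list with
#'   `maximal_change`, `recovery_change`, `recovery_change_normalized`,
#'   `tau`, `trough`, `converged`, `degenerate`, `rss`.
#' @export
extract_metrics <- function(cycle_avg, fit, paradigm, tr, raw_trough = FALSE) {
  maximal <- max(cycle_avg)
  trough <- NA_real_
  if (fit$degenerate) {
    trough <- fit$plateau
  } else if (!is.na(fit$tau)) {
    if (raw_trough) {
      tc <- (seq_along(cycle_avg) - 1) * tr
      trough <- min(cycle_avg[tc >= paradigm$exercise_duration])
    } else {
      trough <- fit$plateau + (fit$peak - fit$plateau) *
        exp(-paradigm$recovery_duration / fit$tau)
    }
  }
  rc <- maximal - trough
  structure(list(maximal_change = maximal,
                 recovery_change = rc,
                 recovery_change_normalized = rc / maximal,
                 tau = fit$tau, trough = trough,
                 converged = fit$converged, degenerate = fit$degenerate,
                 rss = fit$rss),
            class = "oxygenation_metrics")
}
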