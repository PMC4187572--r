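#' Extract the ROI-mean R2* time course
#'
#' Per frame, the mean R2* over all valid voxels of the ROI rectangle
#' across its slices. Because validity masking is whole-run, the set of
#' averaged voxels is the same at every frame.
#'
#' @param r2s An [r2star_series()].
#' @param roi An [roi_spec()].
#' @return An object of class `roi_timecourse`: list with `muscle`,
#'   `times` (s), `r2star_mean` (1/s per frame), `n_voxels` (valid voxel
#'   count), `paradigm`, `acq`.
#' @export
extract_roi_timecourse <- function(r2s, roi) {
  d <- dim(r2s$values)
  xs <- roi$origin[1] + seq_len(roi$width) - 1L
  ys <- roi$origin[2] + seq_len(roi$height) - 1L
  zs <- roi$slices
  if (min(xs) < 1 || max(xs) > d[1] || min(ys) < 1 || max(ys) > d[2] ||
      min(zs) < 1 || max(zs) > d[3])
    stop("ROI '", roi$name, "' exceeds the image bounds")
  valid <- r2s$mask[xs, ys, zs]
  if (!any(valid))
    stop("ROI '", roi$name, "' contains no valid voxels")
  sub <- r2s$values[xs, ys, zs, , drop = FALSE]
  flat <- matrix(sub, prod(dim(sub)[1:3]), d[4])
  mean_tc <- colMeans(flat[as.vector(valid), , drop = FALSE])
  structure(list(muscle = roi$name,
                 times = frame_times(r2s$acq),
                 r2star_mean = mean_tc,
                 n_voxels = sum(valid),
                 paradigm = r2s$paradigm, acq = r2s$acq),
            class = "roi_timecourse")
}

#' Baseline R2* of a time course
#'
#' Mean over the frames whose onset time falls in the half-open window
#' `[window[1], window[2])` seconds — by default 15 to 30 s of the resting
#' baseline, i.e. frames 5-9 at TR = 3 s.
#'
#' @param tc An `roi_timecourse`, or a numeric series (then supply `times`).
#' @param window Length-2 window in seconds.
#' @param times Frame-onset times, required when `tc` is a bare vector.
#' @return Baseline value (1/s).
#' @export
baseline_value <- function(tc, window = c(15, 30), times = NULL) {
  if (inherits(tc, "roi_timecourse")) {
    times <- tc$times
    tc <- tc$r2star_mean
  }
  stopifnot(length(tc) == length(times), window[2] > window[1])
  sel <- times >= window[1] & times < window[2]
  if (!any(sel)) stop("baseline window [", window[1], ", ", window[2],
                      ") contains no frames")
  mean(tc[sel])
}

#' Percent change relative to baseline
#'
#' `(value - baseline) / baseline * 100`. Exercise-induced deoxygenation
#' raises R2*, so the response is a positive excursion.
#'
#' @param values Numeric series (e.g. ROI-mean R2*).
#' @param baseline Baseline value; must be > 0.
#' @return Percent-change series.
#' @export
percent_change <- function(values, baseline) {
  if (!is.finite(baseline) || baseline <= 0)
    stop("baseline must be a positive finite number")
  (values - baseline) / baseline * 100
}

#' Cycle-averaged response
#'
#' Aligns the selected exercise cycles at cycle start and averages them
#' elementwise, yielding one value per within-cycle frame. By default the
#' final three cycles are used, discarding the first cycle's transient
#' (muscle-memory effect). Requires the baseline and cycle durations to be
#' whole numbers of frames.
#'
#' @param values Per-frame series covering the whole run (typically the
#'   percent-change series).
#' @param paradigm An [exercise_paradigm()] object.
#' @param tr Repetition time in seconds.
#' @param cycles 0-based indices of the cycles to average; default the
#'   last three.
#' @return Numeric vector of length `cycle_duration / tr`, with attribute
#'   `within_cycle_times` (seconds since cycle start).
#' @export
cycle_average <- function(values, paradigm, tr,
                          cycles = (paradigm$n_cycles - 3):(paradigm$n_cycles - 1)) {
  cyc <- cycle_duration(paradigm)
  fpc <- cyc / tr
  f0 <- paradigm$baseline_duration / tr
  if (abs(fpc - round(fpc)) > 1e-9 || abs(f0 - round(f0)) > 1e-9)
    stop("cycle boundaries do not align with the frame grid")
  fpc <- as.integer(round(fpc)); f0 <- as.integer(round(f0))
  stopifnot(all(cycles >= 0), all(cycles < paradigm$n_cycles),
            length(cycles) >= 1)
  if (f0 + paradigm$n_cycles * fpc > length(values))
    stop("series too short for the paradigm")
  m <- vapply(cycles, function(k) values[f0 + k * fpc + seq_len(fpc)],
              numeric(fpc))
  out <- rowMeans(m)
  attr(out, "within_cycle_times") <- (seq_len(fpc) - 1) * tr
  out
}

#' Cycle-averaged percent-change time course of an ROI
#'
#' Convenience wrapper chaining [baseline_value()], [percent_change()] and
#' [cycle_average()] on an extracted ROI time course.
#'
#' @param tc An `roi_timecourse`.
#' @param baseline_window Baseline window in seconds.
#' @param cycles Cycles to average (0-based); default the last three.
#' @return List with `baseline` (1/s), `percent_change` (per frame) and
#'   `cycle_average` (per within-cycle frame).
#' @export
roi_cycle_response <- function(tc, baseline_window = c(15, 30), cycles = NULL) {
  b <- baseline_value(tc, window = baseline_window)
  pct <- percent_change(tc$r2star_mean, b)
  if (is.null(cycles))
    cycles <- (tc$paradigm$n_cycles - 3):(tc$paradigm$n_cycles - 1)
  ca <- cycle_average(pct, tc$paradigm, tc$acq$tr, cycles = cycles)
  list(muscle = tc$muscle, baseline = b, percent_change = pct,
       cycle_average = ca)
}

#' Export ROI time courses to a tidy data frame
#'
#' One row per (muscle, frame): columns muscle, frame, time, r2star,
#' pct_change.
#'
#' @param tcs List of `roi_timecourse` objects.
#' @param baseline_window Baseline window in seconds.
#' @return Data frame.
#' @export
timecourse_table <- function(tcs, baseline_window = c(15, 30)) {
  do.call(rbind, lapply(tcs, function(tc) {
    b <- baseline_value(tc, window = baseline_window)
    data.frame(muscle = tc$muscle,
               frame = seq_along(tc$times) - 1L,
               time = tc$times,
               r2star = tc$r2star_mean,
               pct_change = percent_change(tc$r2star_mean, b))
  }))
}
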