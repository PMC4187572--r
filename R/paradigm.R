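#' Acquisition parameters for a dual-echo EPI run
#'
#' Bundles the imaging-sequence parameters every other stage needs: the
#' repetition time that spaces the dynamic frames, the two echo times used
#' for two-point R2* estimation, and the matrix/field-of-view geometry that
#' fixes the voxel size. Defaults are a 3 T dual-gradient-echo EPI protocol
#' for the calf: TR 3 s, TE 21/60 ms, 80 x 80 matrix over a 200 x 200 mm
#' field of view (2.5 mm in-plane voxels), ten contiguous 5 mm slices, and
#' 300 dynamic frames (900 s).
#'
#' @param tr Repetition time in seconds per volume.
#' @param te1,te2 First and second echo times in seconds; `te2 > te1`.
#' @param matrix_x,matrix_y In-plane matrix size in voxels.
#' @param fov_x,fov_y In-plane field of view in mm.
#' @param n_slices Number of slices.
#' @param slice_thickness Slice thickness in mm.
#' @param n_frames Number of dynamic frames (volumes per echo).
#' @return An object of class `acquisition_params`.
#' @export
#' @examples
#' acq <- acquisition_params()
#' voxel_size(acq)  # 2.5 2.5 5
acquisition_params <- function(tr = 3, te1 = 0.021, te2 = 0.060,
                               matrix_x = 80, matrix_y = 80,
                               fov_x = 200, fov_y = 200,
                               n_slices = 10, slice_thickness = 5,
                               n_frames = 300) {
  stopifnot(tr > 0, te1 > 0, te2 > te1,
            matrix_x >= 1, matrix_y >= 1, fov_x > 0, fov_y > 0,
            n_slices >= 1, slice_thickness > 0, n_frames >= 1)
  structure(list(tr = tr, te1 = te1, te2 = te2,
                 matrix_x = as.integer(matrix_x), matrix_y = as.integer(matrix_y),
                 fov_x = fov_x, fov_y = fov_y,
                 n_slices = as.integer(n_slices),
                 slice_thickness = slice_thickness,
                 n_frames = as.integer(n_frames)),
            class = "acquisition_params")
}

#' Voxel edge lengths in mm
#'
#' In-plane edges are `fov / matrix`; the through-plane edge is the slice
#' thickness.
#'
#' @param acq An [acquisition_params()] object.
#' @return Named numeric vector `c(x, y, z)` in mm.
#' @export
voxel_size <- function(acq) {
  c(x = acq$fov_x / acq$matrix_x,
    y = acq$fov_y / acq$matrix_y,
    z = acq$slice_thickness)
}

#' Block-design exercise paradigm
#'
#' A resting baseline followed by `n_cycles` identical stimulus cycles,
#' each a contraction block followed by a passive recovery block. Defaults
#' are the plantar-flexion protocol: 60 s baseline then four 210 s cycles
#' of 90 s exercise (0.3 Hz contractions) + 120 s recovery, 900 s total.
#'
#' @param baseline_duration Seconds of rest before the first cycle.
#' @param n_cycles Number of exercise cycles.
#' @param exercise_duration Seconds of contraction per cycle.
#' @param recovery_duration Seconds of recovery per cycle.
#' @param contraction_rate Contraction rate in Hz (metadata only; the
#'   signal model does not resolve individual contractions).
#' @return An object of class `exercise_paradigm`.
#' @export
exercise_paradigm <- function(baseline_duration = 60, n_cycles = 4,
                              exercise_duration = 90, recovery_duration = 120,
                              contraction_rate = 0.3) {
  stopifnot(baseline_duration > 0, n_cycles >= 1,
            exercise_duration > 0, recovery_duration > 0)
  structure(list(baseline_duration = baseline_duration,
                 n_cycles = as.integer(n_cycles),
                 exercise_duration = exercise_duration,
                 recovery_duration = recovery_duration,
                 contraction_rate = contraction_rate),
            class = "exercise_paradigm")
}

#' @rdname exercise_paradigm
#' @param paradigm An `exercise_paradigm` object.
#' @export
cycle_duration <- function(paradigm) {
  paradigm$exercise_duration + paradigm$recovery_duration
}

#' @rdname exercise_paradigm
#' @export
total_duration <- function(paradigm) {
  paradigm$baseline_duration + paradigm$n_cycles * cycle_duration(paradigm)
}

#' Acquisition time of a frame
#'
#' Frames are timestamped at acquisition onset: frame `i` (0-based) starts
#' at `i * TR` seconds.
#'
#' @param frame_index 0-based frame index (vectorised).
#' @param acq An [acquisition_params()] object.
#' @return Time in seconds.
#' @export
frame_time <- function(frame_index, acq) {
  if (any(frame_index < 0) || any(frame_index >= acq$n_frames))
    stop("frame_index out of range [0, ", acq$n_frames - 1, "]")
  frame_index * acq$tr
}

#' Onset times of all frames
#' @inheritParams frame_time
#' @return Numeric vector of length `n_frames`.
#' @export
frame_times <- function(acq) (seq_len(acq$n_frames) - 1) * acq$tr

#' Assign each frame to a paradigm phase
#'
#' Partitions the frame grid into baseline, exercise, and recovery phases
#' using half-open `[start, end)` intervals on frame-onset times, so each
#' frame belongs to exactly one phase. Frames beyond the paradigm (if the
#' acquisition outlasts it) are labelled `"post"` and ignored by the
#' downstream analysis.
#'
#' @param paradigm An [exercise_paradigm()] object.
#' @param acq An [acquisition_params()] object.
#' @return A data frame with columns `frame` (0-based), `time` (s), `phase`
#'   (factor: baseline/exercise/recovery/post), and `cycle` (0-based cycle
#'   index, `NA` outside cycles).
#' @export
classify_frames <- function(paradigm, acq) {
  if (total_duration(paradigm) > acq$n_frames * acq$tr)
    stop("paradigm (", total_duration(paradigm),
         " s) is longer than the acquisition (", acq$n_frames * acq$tr, " s)")
  t <- frame_times(acq)
  base <- paradigm$baseline_duration
  cyc <- cycle_duration(paradigm)
  phase <- rep("post", length(t))
  cycle <- rep(NA_integer_, length(t))
  phase[t < base] <- "baseline"
  in_cycles <- t >= base & t < total_duration(paradigm)
  tc <- t[in_cycles] - base
  k <- pmin(floor(tc / cyc), paradigm$n_cycles - 1)
  within <- tc - k * cyc
  phase[in_cycles] <- ifelse(within < paradigm$exercise_duration,
                             "exercise", "recovery")
  cycle[in_cycles] <- as.integer(k)
  data.frame(frame = seq_along(t) - 1L, time = t,
             phase = factor(phase, levels = c("baseline", "exercise",
                                              "recovery", "post")),
             cycle = cycle)
}

#' Read or write an acquisition + paradigm configuration
#'
#' The configuration is a YAML file with top-level keys `acquisition` and
#' `paradigm` whose sub-keys mirror the argument names of
#' [acquisition_params()] and [exercise_paradigm()]. Units: seconds, mm, Hz.
#'
#' @param path Path to a YAML file.
#' @return For `read_study_config`, a list with elements `acq` and
#'   `paradigm` (plus any `rois` present, see [roi_spec()]).
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- list(acq = do.call(acquisition_params, cfg$acquisition),
              paradigm = do.call(exercise_paradigm, cfg$paradigm))
  if (!is.null(cfg$rois))
    out$rois <- lapply(cfg$rois, function(r) do.call(roi_spec, r))
  out
}

#' @rdname read_study_config
#' @param acq,paradigm Objects to serialise.
#' @param rois Optional named list of [roi_spec()] objects.
#' @export
write_study_config <- function(acq, paradigm, path, rois = NULL) {
  cfg <- list(acquisition = unclass(acq), paradigm = unclass(paradigm))
  if (!is.null(rois)) cfg$rois <- lapply(rois, unclass)
  yaml::write_yaml(cfg, path)
  invisible(path)
}
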