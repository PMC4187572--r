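#' Tissue compartment of the calf phantom
#'
#' A rectangular in-plane region replicated over a slice range, with a
#' proton-density-like signal at TE = 0 (`s0`) and a baseline effective
#' transverse relaxation rate. Everything not covered by a muscle tissue is
#' background.
#'
#' @param label One of `"soleus"`, `"medial_gastrocnemius"`,
#'   `"lateral_gastrocnemius"`, `"background"`.
#' @param s0 Signal at TE = 0, arbitrary units; > 0.
#' @param r2star_baseline Baseline R2* in 1/s; > 0.
#' @param origin 1-based `c(x, y)` voxel of the rectangle's corner
#'   (ignored for background).
#' @param width,height Rectangle size in voxels.
#' @param slices 1-based slice indices the rectangle occupies.
#' @return An object of class `tissue_spec`.
#' @export
tissue_spec <- function(label, s0, r2star_baseline,
                        origin = NULL, width = NULL, height = NULL,
                        slices = NULL) {
  stopifnot(s0 > 0, r2star_baseline > 0)
  structure(list(label = label, s0 = s0, r2star_baseline = r2star_baseline,
                 origin = origin, width = width, height = height,
                 slices = slices),
            class = "tissue_spec")
}

#' Rectangular muscle region of interest
#'
#' ROIs are per-slice rectangles replicated across a slice range,
#' mirroring manual rectangular ROI placement on the functional images.
#'
#' @param name ROI name.
#' @param origin 1-based `c(x, y)` corner voxel.
#' @param width,height Size in voxels.
#' @param slices 1-based slice indices.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(name, origin, width, height, slices) {
  stopifnot(length(origin) == 2, width >= 1, height >= 1, length(slices) >= 1)
  structure(list(name = name, origin = as.integer(origin),
                 width = as.integer(width), height = as.integer(height),
                 slices = as.integer(slices)),
            class = "roi_spec")
}

#' Calf phantom presets
#'
#' Two fixed geometries. `"full"`: 80 x 80 matrix, 200 mm FOV (2.5 mm
#' voxels), ten 5 mm slices, with ROI rectangles of the published sizes —
#' medial gastrocnemius 32 x 6, lateral gastrocnemius 16 x 6 (combined
#' gastrocnemius 48 x 6) and soleus 25 x 6 voxels, on the middle six
#' slices. `"fast"`: a reduced 40 x 40 matrix over the same FOV (5 mm
#' voxels) with ROI sizes halved, for quick simulations.
#'
#' Phantom muscle rectangles extend beyond their ROI rectangles by a margin
#' at least as wide as the smoothing-kernel radius, emulating conservative
#' ROI placement away from muscle borders, so spatial smoothing does not
#' mix background signal into the ROIs. The two gastrocnemius heads abut.
#' Default tissue values are fixed constants: muscle R2* 30 1/s over
#' background 25 1/s, with 2:1 s0 contrast.
#'
#' @param preset `"full"` or `"fast"`.
#' @return `phantom_acquisition`: an [acquisition_params()] object.
#'   `phantom_tissues`: a named list of [tissue_spec()] (background last).
#'   `roi_set`: a named list of [roi_spec()] for soleus, medial and lateral
#'   gastrocnemius, and the combined gastrocnemius.
#' @export
phantom_acquisition <- function(preset = c("full", "fast")) {
  preset <- match.arg(preset)
  if (preset == "full") acquisition_params()
  else acquisition_params(matrix_x = 40, matrix_y = 40)
}

#' @rdname phantom_acquisition
#' @param s0_muscle,s0_background Signal at TE = 0, arbitrary units.
#' @param r2star_muscle,r2star_background Baseline R2* in 1/s.
#' @export
phantom_tissues <- function(preset = c("full", "fast"),
                            s0_muscle = 1000, s0_background = 500,
                            r2star_muscle = 30, r2star_background = 25) {
  preset <- match.arg(preset)
  all_slices <- 1:10
  geo <- if (preset == "full") {
    list(medial_gastrocnemius  = list(c(8, 13), 35, 12),
         lateral_gastrocnemius = list(c(43, 13), 19, 12),
         soleus                = list(c(23, 38), 31, 12))
  } else {
    list(medial_gastrocnemius  = list(c(4, 7), 18, 7),
         lateral_gastrocnemius = list(c(22, 7), 10, 7),
         soleus                = list(c(12, 19), 16, 7))
  }
  out <- lapply(names(geo), function(nm) {
    g <- geo[[nm]]
    tissue_spec(nm, s0_muscle, r2star_muscle,
                origin = g[[1]], width = g[[2]], height = g[[3]],
                slices = all_slices)
  })
  names(out) <- names(geo)
  out$background <- tissue_spec("background", s0_background, r2star_background)
  out
}

#' @rdname phantom_acquisition
#' @export
roi_set <- function(preset = c("full", "fast")) {
  preset <- match.arg(preset)
  mid6 <- 3:8  # middle six of ten slices
  geo <- if (preset == "full") {
    list(medial_gastrocnemius  = list(c(11, 16), 32, 6),
         lateral_gastrocnemius = list(c(43, 16), 16, 6),
         gastrocnemius         = list(c(11, 16), 48, 6),
         soleus                = list(c(26, 41), 25, 6))
  } else {
    list(medial_gastrocnemius  = list(c(6, 9), 16, 3),
         lateral_gastrocnemius = list(c(22, 9), 8, 3),
         gastrocnemius         = list(c(6, 9), 24, 3),
         soleus                = list(c(14, 21), 12, 3))
  }
  out <- lapply(names(geo), function(nm) {
    g <- geo[[nm]]
    roi_spec(nm, g[[1]], g[[2]], g[[3]], mid6)
  })
  names(out) <- names(geo)
  out
}

# 3D integer label array: index into the tissue list; background fills the
# remainder. Errors if a muscle rectangle overflows the matrix or overlaps
# another muscle.
phantom_labels <- function(acq, tissues) {
  dims <- c(acq$matrix_x, acq$matrix_y, acq$n_slices)
  bg <- which(vapply(tissues, function(t) t$label == "background", logical(1)))
  if (length(bg) != 1) stop("exactly one background tissue is required")
  lab <- array(bg, dim = dims)
  claimed <- array(FALSE, dim = dims)
  for (i in seq_along(tissues)) {
    ts <- tissues[[i]]
    if (ts$label == "background") next
    xs <- ts$origin[1] + seq_len(ts$width) - 1
    ys <- ts$origin[2] + seq_len(ts$height) - 1
    if (max(xs) > dims[1] || max(ys) > dims[2] || max(ts$slices) > dims[3] ||
        min(xs) < 1 || min(ys) < 1 || min(ts$slices) < 1)
      stop("tissue '", ts$label, "' exceeds the matrix bounds")
    if (any(claimed[xs, ys, ts$slices]))
      stop("tissue '", ts$label, "' overlaps another muscle region")
    claimed[xs, ys, ts$slices] <- TRUE
    lab[xs, ys, ts$slices] <- i
  }
  lab
}
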