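#' Two-point R2* from a dual-echo signal pair
#'
#' The unique two-echo solution of the monoexponential decay
#' `S(TE) = s0 * exp(-TE * R2*)`:
#' `R2* = ln(S1 / S2) / (TE2 - TE1)`.
#' Pairs where either signal is at or below the positivity threshold
#' `epsilon` return `NA` (flagged invalid) rather than propagating
#' non-finite values silently. The estimate is invariant to common signal
#' scaling (coil gain).
#'
#' @param s1,s2 Signals at the first and second echo (vectorised).
#' @param te1,te2 Echo times in seconds, `te2 > te1`.
#' @param epsilon Positivity threshold in signal units.
#' @return R2* in 1/s; `NA` where invalid.
#' @export
#' @examples
#' r2star_from_dual_echo(1000, 400, 0.021, 0.060)  # ~23.49
r2star_from_dual_echo <- function(s1, s2, te1, te2, epsilon = 0) {
  if (te2 <= te1) stop("te2 must exceed te1")
  ok <- is.finite(s1) & is.finite(s2) & s1 > epsilon & s2 > epsilon
  out <- rep(NA_real_, length(ok))
  out[ok] <- log(s1[ok] / s2[ok]) / (te2 - te1)
  out
}

#' R2* time series from a dual-echo series
#'
#' Applies the two-point R2* solution voxelwise and framewise. A voxel is
#' valid only if both echoes exceed the threshold at **every** frame;
#' invalid voxels are masked for the whole run (all frames `NA`), so
#' extracted time courses never have holes. The default threshold is
#' `1e-6` times the median signal over both echo series — a positivity
#' guard for the logarithm.
#'
#' @param series A `dual_echo_series`.
#' @param epsilon Signal threshold; `NULL` for the default.
#' @return An object of class `r2star_series`: list with `values` (4D
#'   array, 1/s), `mask` (3D logical, TRUE = valid), `acq`, `paradigm`.
#' @export
r2star_series <- function(series, epsilon = NULL) {
  e1 <- series$echo1
  e2 <- series$echo2
  if (!identical(dim(e1), dim(e2)))
    stop("echo arrays have mismatched geometry")
  if (is.null(epsilon))
    epsilon <- 1e-6 * stats::median(c(e1, e2))
  v <- r2star_from_dual_echo(e1, e2, series$acq$te1, series$acq$te2, epsilon)
  dim(v) <- dim(e1)
  d <- dim(v)
  flat <- matrix(v, prod(d[1:3]), d[4])
  mask_vec <- rowSums(is.na(flat)) == 0L
  flat[!mask_vec, ] <- NA_real_
  dim(flat) <- d
  structure(list(values = flat,
                 mask = array(mask_vec, dim = d[1:3]),
                 acq = series$acq, paradigm = series$paradigm),
            class = "r2star_series")
}

#' Write an R2* series as NIfTI-1
#'
#' Writes `<prefix>_r2star.nii.gz` (values, 1/s, float64) and
#' `<prefix>_mask.nii.gz` (validity mask, 0/1).
#'
#' @param r2s An `r2star_series`.
#' @param prefix Output path prefix.
#' @export
write_r2star <- function(r2s, prefix) {
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  vox <- voxel_size(r2s$acq)
  img <- RNifti::asNifti(r2s$values)
  img <- RNifti::`pixdim<-`(img, c(vox, r2s$acq$tr))
  RNifti::writeNifti(img, paste0(prefix, "_r2star.nii.gz"),
                     datatype = "double")
  m <- RNifti::asNifti(array(as.integer(r2s$mask), dim = dim(r2s$mask)))
  m <- RNifti::`pixdim<-`(m, vox)
  RNifti::writeNifti(m, paste0(prefix, "_mask.nii.gz"), datatype = "uint8")
  invisible(prefix)
}
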