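#' Noise model for the synthetic generator
#'
#' Rician noise is the magnitude-MRI model: the noisy magnitude is
#' `sqrt((S + n1)^2 + n2^2)` with `n1, n2 ~ Normal(0, sigma)` drawn
#' independently per echo, frame and voxel. Gaussian (`S + n1`) and
#' noise-free variants are provided for oracle tests. Either `sigma` (in
#' signal units) or `snr` must be given; SNR is defined as the first-echo
#' muscle baseline signal divided by `sigma`.
#'
#' @param model `"rician"`, `"gaussian"` or `"none"`.
#' @param sigma Gaussian component standard deviation, signal units; >= 0.
#' @param snr Signal-to-noise ratio; converted to `sigma` at generation
#'   time from the reference (soleus) first-echo baseline signal.
#' @param seed Integer seed; identical seeds give bit-identical datasets.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(model = c("rician", "gaussian", "none"),
                       sigma = NULL, snr = NULL, seed = 1L) {
  model <- match.arg(model)
  if (model != "none") {
    if (is.null(sigma) && is.null(snr))
      stop("give either sigma or snr for a noisy model")
    if (!is.null(sigma) && sigma < 0) stop("sigma must be >= 0")
    if (!is.null(snr) && snr <= 0) stop("snr must be > 0")
  }
  structure(list(model = model, sigma = sigma, snr = snr,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

# sigma implied by an SNR: reference is the soleus first-echo baseline signal
snr_to_sigma <- function(snr, acq, tissues, reference = "soleus") {
  ref <- tissues[[reference]]
  ref$s0 * exp(-acq$te1 * ref$r2star_baseline) / snr
}

# evaluate thunk with a temporary RNG state; restores the caller's state
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic dual-echo EPI dataset
#'
#' Builds the calf phantom, injects the per-muscle percent-change R2*
#' dynamics, and synthesises both echo images frame by frame under the
#' monoexponential decay model `S(TE, t) = s0 * exp(-TE * R2*(t))` with
#' `R2*(t) = r2star_baseline * (1 + p(t)/100)`, then applies the requested
#' noise. Background tissue has `p(t) = 0`.
#'
#' @param acq An [acquisition_params()] object.
#' @param paradigm An [exercise_paradigm()] object; must fit within the
#'   acquisition.
#' @param tissues Named list of [tissue_spec()] (see [phantom_tissues()]).
#' @param truth A [ground_truth()] list keyed by muscle label.
#' @param noise A [noise_spec()].
#' @return An object of class `dual_echo_series`: list with 4D arrays
#'   `echo1`, `echo2` (x, y, slice, frame), plus `acq`, `paradigm`,
#'   `tissues`, `truth`, `noise` and the 3D `labels` array.
#' @export
#' @examples
#' acq <- phantom_acquisition("fast")
#' sim <- generate_dual_echo(acq, exercise_paradigm(),
#'                           phantom_tissues("fast"), ground_truth(),
#'                           noise_spec("none"))
#' dim(sim$echo1)
generate_dual_echo <- function(acq, paradigm, tissues, truth,
                               noise = noise_spec("rician", snr = 50)) {
  if (total_duration(paradigm) > acq$n_frames * acq$tr)
    stop("paradigm is longer than the acquisition")
  lab <- phantom_labels(acq, tissues)
  times <- frame_times(acq)
  nt <- acq$n_frames
  ntis <- length(tissues)

  # per-tissue, per-frame lookup tables of the noiseless echo signals
  pct <- matrix(0, ntis, nt)
  for (i in seq_len(ntis)) {
    labi <- tissues[[i]]$label
    if (labi != "background" && !is.null(truth[[labi]]))
      pct[i, ] <- percent_change_profile(times, paradigm, truth[[labi]])
  }
  s0 <- vapply(tissues, `[[`, numeric(1), "s0")
  r2b <- vapply(tissues, `[[`, numeric(1), "r2star_baseline")
  r2t <- r2b * (1 + pct / 100)             # ntis x nt
  lut1 <- s0 * exp(-acq$te1 * r2t)
  lut2 <- s0 * exp(-acq$te2 * r2t)

  labv <- as.vector(lab)
  dims <- c(dim(lab), nt)
  e1 <- lut1[labv, , drop = FALSE]
  e2 <- lut2[labv, , drop = FALSE]

  sigma <- switch(noise$model,
                  none = 0,
                  if (!is.null(noise$sigma)) noise$sigma
                  else snr_to_sigma(noise$snr, acq, tissues))
  if (noise$model != "none" && sigma > 0) {
    nvox <- length(e1)
    e <- with_seed(noise$seed, {
      if (noise$model == "rician") {
        list(sqrt((e1 + rnorm(nvox, 0, sigma))^2 + rnorm(nvox, 0, sigma)^2),
             sqrt((e2 + rnorm(nvox, 0, sigma))^2 + rnorm(nvox, 0, sigma)^2))
      } else {
        list(e1 + rnorm(nvox, 0, sigma), e2 + rnorm(nvox, 0, sigma))
      }
    })
    e1 <- e[[1]]; e2 <- e[[2]]
  }
  dim(e1) <- dims
  dim(e2) <- dims
  structure(list(echo1 = e1, echo2 = e2, acq = acq, paradigm = paradigm,
                 tissues = tissues, truth = truth, noise = noise,
                 labels = lab),
            class = "dual_echo_series")
}

#' Write / read a dual-echo dataset as NIfTI-1 plus sidecars
#'
#' Writes `<prefix>_echo1.nii.gz` and `<prefix>_echo2.nii.gz` (float64, so
#' arrays round-trip bit-exactly), the ground-truth table as
#' `<prefix>_truth.csv`, and the acquisition/paradigm config as
#' `<prefix>_config.yaml`.
#'
#' @param series A `dual_echo_series`.
#' @param prefix Output path prefix.
#' @return `write_dual_echo`: the prefix, invisibly. `read_dual_echo`: a
#'   `dual_echo_series` (without tissue/truth/noise provenance beyond the
#'   truth table).
#' @export
write_dual_echo <- function(series, prefix) {
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  vox <- voxel_size(series$acq)
  for (e in 1:2) {
    img <- RNifti::asNifti(series[[paste0("echo", e)]])
    img <- RNifti::`pixdim<-`(img, c(vox, series$acq$tr))
    RNifti::writeNifti(img, paste0(prefix, "_echo", e, ".nii.gz"),
                       datatype = "double")
  }
  utils::write.csv(truth_table(series$truth),
                   paste0(prefix, "_truth.csv"), row.names = FALSE)
  write_study_config(series$acq, series$paradigm,
                     paste0(prefix, "_config.yaml"))
  invisible(prefix)
}

#' @rdname write_dual_echo
#' @export
read_dual_echo <- function(prefix) {
  for (e in 1:2) {
    f <- paste0(prefix, "_echo", e, ".nii.gz")
    if (!file.exists(f)) stop("missing echo file: ", f)
  }
  cfg <- read_study_config(paste0(prefix, "_config.yaml"))
  img1 <- RNifti::readNifti(paste0(prefix, "_echo1.nii.gz"))
  img2 <- RNifti::readNifti(paste0(prefix, "_echo2.nii.gz"))
  e1 <- array(as.numeric(img1), dim = dim(img1))
  e2 <- array(as.numeric(img2), dim = dim(img2))
  truth_file <- paste0(prefix, "_truth.csv")
  truth <- if (file.exists(truth_file)) {
    tt <- utils::read.csv(truth_file)
    structure(lapply(seq_len(nrow(tt)), function(i)
      oxygenation_truth(tt$maximal_change[i], tt$recovery_deficit[i], tt$tau[i])),
      names = tt$muscle, class = "ground_truth")
  } else NULL
  structure(list(echo1 = e1, echo2 = e2, acq = cfg$acq,
                 paradigm = cfg$paradigm, truth = truth),
            class = "dual_echo_series")
}
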