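# small hand-built R2* series: constant value per voxel block
flat_r2s <- function(vals3d, nt = 10, tr = 3) {
  d <- dim(vals3d)
  acq <- acquisition_params(matrix_x = d[1], matrix_y = d[2],
                            n_slices = d[3], n_frames = nt, tr = tr,
                            fov_x = d[1] * 2.5, fov_y = d[2] * 2.5)
  v <- array(rep(vals3d, nt), dim = c(d, nt))
  structure(list(values = v, mask = array(TRUE, d), acq = acq,
                 paradigm = exercise_paradigm(baseline_duration = 3,
                                              n_cycles = 1,
                                              exercise_duration = 12,
                                              recovery_duration = 15)),
            class = "r2star_series")
}

test_that("ROI means average the right voxels", {
  vals <- array(30, dim = c(8, 8, 4))
  r2s <- flat_r2s(vals)
  roi <- roi_spec("m", c(2, 2), 4, 2, 1:4)
  tc <- extract_roi_timecourse(r2s, roi)
  expect_equal(tc$r2star_mean, rep(30, 10))
  expect_equal(tc$n_voxels, 4 * 2 * 4)
  # half at a, half at b -> (a + b) / 2
  vals2 <- array(10, dim = c(8, 8, 4)); vals2[2:3, 2:3, ] <- 20
  roi2 <- roi_spec("m", c(2, 2), 4, 2, 1:4)  # half covers the 20-block
  tc2 <- extract_roi_timecourse(flat_r2s(vals2), roi2)
  expect_equal(tc2$r2star_mean, rep(15, 10))
  # out-of-bounds and fully masked ROIs error
  expect_error(extract_roi_timecourse(r2s, roi_spec("m", c(7, 7), 4, 2, 1:4)),
               "bounds")
  r2m <- r2s; r2m$mask[2:5, 2:3, ] <- FALSE
  expect_error(extract_roi_timecourse(r2m, roi), "no valid voxels")
})

test_that("baseline window selects frames with onset in [15, 30) s", {
  tc <- seq_len(20)  # frame i has value i (frame index i-1)
  times <- (0:19) * 3
  expect_equal(baseline_value(rep(4, 20), times = times), 4)
  # frames 5..9 selected: values 6..10
  expect_equal(baseline_value(tc, times = times), mean(6:10))
  v <- rep(0, 20); v[6:10] <- c(10, 10, 10, 10, 20)
  expect_equal(baseline_value(v, times = times), 12)
  expect_error(baseline_value(tc, window = c(16, 17), times = times),
               "no frames")
})

test_that("percent change is a baseline-relative rescaling", {
  expect_equal(percent_change(30, 30), 0)
  expect_equal(percent_change(31.5, 30), 5)
  expect_error(percent_change(1, 0), "baseline")
  expect_error(percent_change(1, -3), "baseline")
})

test_that("cycle averaging aligns cycles and averages the selected ones", {
  p <- exercise_paradigm(baseline_duration = 6, n_cycles = 4,
                         exercise_duration = 6, recovery_duration = 6)
  tr <- 3
  fpc <- 4
  base <- rep(0, 2)
  cyc_vals <- function(v) rep(v, each = fpc)
  series <- c(base, cyc_vals(9), cyc_vals(1), cyc_vals(2), cyc_vals(3))
  # default: last three cycles -> mean of 1, 2, 3
  expect_equal(as.numeric(cycle_average(series, p, tr)), rep(2, fpc))
  # identical cycles: average equals any single cycle
  series2 <- c(base, rep(c(5, 6, 7, 8), 4))
  expect_equal(as.numeric(cycle_average(series2, p, tr)), c(5, 6, 7, 8))
  attr_t <- attr(cycle_average(series2, p, tr), "within_cycle_times")
  expect_equal(attr_t, c(0, 3, 6, 9))
  # misaligned grid errors
  p_bad <- exercise_paradigm(baseline_duration = 6, n_cycles = 4,
                             exercise_duration = 5, recovery_duration = 6)
  expect_equal(cycle_duration(p_bad), 11)
  expect_error(cycle_average(series, p_bad, tr), "align")
})

test_that("gastrocnemius ROI mean is the voxel-weighted mean of its two heads", {
  sim <- fast_noiseless()
  r2s <- r2star_series(sim)
  rois <- roi_set("fast")
  med <- extract_roi_timecourse(r2s, rois$medial_gastrocnemius)
  lat <- extract_roi_timecourse(r2s, rois$lateral_gastrocnemius)
  gas <- extract_roi_timecourse(r2s, rois$gastrocnemius)
  w <- c(med$n_voxels, lat$n_voxels)
  expect_equal(w / sum(w), c(32, 16) / 48)  # 2:1 voxel weighting
  expect_equal(gas$r2star_mean,
               (med$r2star_mean * w[1] + lat$r2star_mean * w[2]) / sum(w),
               tolerance = 1e-12)
})

test_that("percent change and cycle averaging commute under a shared baseline", {
  sim <- fast_noiseless()
  r2s <- r2star_series(sim)
  tc <- extract_roi_timecourse(r2s, roi_set("fast")$soleus)
  b <- baseline_value(tc)
  a <- cycle_average(percent_change(tc$r2star_mean, b), sim$paradigm, 3)
  b2 <- percent_change(cycle_average(tc$r2star_mean, sim$paradigm, 3), b)
  expect_equal(as.numeric(a), as.numeric(b2), tolerance = 1e-12)
})

test_that("the noiseless pipeline reproduces the injected profile exactly", {
  sim <- fast_noiseless()
  r2s <- r2star_series(sim)
  resp <- roi_cycle_response(extract_roi_timecourse(r2s, roi_set("fast")$soleus))
  truth_cycle <- percent_change_profile(
    60 + 210 + attr(resp$cycle_average, "within_cycle_times"),
    sim$paradigm, sim$truth$soleus)
  expect_equal(as.numeric(resp$cycle_average), truth_cycle, tolerance = 1e-10)
  expect_equal(resp$baseline, 30, tolerance = 1e-10)
})
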