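test_that("injected percent-change profile has the closed-form cycle shape", {
  p <- exercise_paradigm()
  # baseline is flat zero
  tr5 <- oxygenation_truth(5, 4, 40)
  expect_equal(percent_change_profile(c(0, 15, 59.9), p, tr5), c(0, 0, 0))
  # near-instantaneous recovery returns to A - D immediately
  tr0 <- oxygenation_truth(5, 5, 1e-9)
  expect_equal(percent_change_profile(60 + 90 + 1, p, tr0), 0)
  # closed form at t_rec = 120 s: (A-D) + D exp(-3) with A=5, D=4, tau=40
  t_end <- 60 + 210 - 1e-9  # just inside the first recovery
  expect_equal(percent_change_profile(t_end, p, tr5),
               1 + 4 * exp(-120 / 40), tolerance = 1e-6)
  # cycle-periodic after cycle 1: cycles 2,3,4 are identical
  times_in_cycle <- seq(0, 209.9, by = 0.5)
  prof <- function(k) percent_change_profile(60 + k * 210 + times_in_cycle, p, tr5)
  expect_equal(prof(1), prof(2))
  expect_equal(prof(2), prof(3))
  # exercise ramp peaks at A at the exercise -> recovery boundary
  expect_equal(percent_change_profile(60 + 90, p, tr5), 5)
})

test_that("noiseless dual-echo signals follow monoexponential decay", {
  acq <- phantom_acquisition("fast")
  sim <- fast_noiseless()
  # muscle baseline voxel: S = s0 exp(-TE * 30)
  lab <- sim$labels
  sol <- which(lab == which(names(sim$tissues) == "soleus"), arr.ind = TRUE)[1, ]
  s1 <- sim$echo1[sol[1], sol[2], sol[3], 1]
  s2 <- sim$echo2[sol[1], sol[2], sol[3], 1]
  expect_equal(s1, 1000 * exp(-0.021 * 30), tolerance = 1e-12)  # 532.592
  expect_equal(s2, 1000 * exp(-0.060 * 30), tolerance = 1e-12)  # 165.299
  # log-ratio identity recovers R2*(t) exactly at every frame
  expect_equal(log(s1 / s2) / (0.060 - 0.021), 30, tolerance = 1e-12)
})

test_that("generation is seed-deterministic and seed-sensitive", {
  acq <- phantom_acquisition("fast")
  mk <- function(seed) generate_dual_echo(
    acq, exercise_paradigm(), phantom_tissues("fast"), ground_truth(),
    noise_spec("rician", snr = 50, seed = seed))
  a <- mk(7); b <- mk(7); c <- mk(8)
  expect_identical(a$echo1, b$echo1)
  expect_identical(a$echo2, b$echo2)
  expect_false(identical(a$echo1, c$echo1))
  # generation does not disturb the caller's RNG stream
  set.seed(42); before <- rnorm(1)
  set.seed(42); invisible(mk(7)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("Rician noise at high SNR biases the mean signal by about sigma^2 / (2 S)", {
  s <- 500; sigma <- 10
  set.seed(1)
  n <- 2e5
  noisy <- sqrt((s + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2)
  expect_equal(mean(noisy) - s, sigma^2 / (2 * s), tolerance = 0.15)
})

test_that("datasets round-trip through the NIfTI writer/reader bit-exactly", {
  acq <- acquisition_params(matrix_x = 8, matrix_y = 8, n_slices = 3,
                            n_frames = 4, tr = 3)
  p <- exercise_paradigm(baseline_duration = 3, n_cycles = 1,
                         exercise_duration = 3, recovery_duration = 6)
  tis <- list(soleus = tissue_spec("soleus", 1000, 30, c(2, 2), 4, 4, 1:3),
              background = tissue_spec("background", 500, 25))
  sim <- generate_dual_echo(acq, p, list(soleus = tis$soleus,
                                         background = tis$background),
                            list(soleus = oxygenation_truth(5)),
                            noise_spec("rician", sigma = 5, seed = 3))
  prefix <- file.path(withr::local_tempdir(), "sim")
  write_dual_echo(sim, prefix)
  back <- read_dual_echo(prefix)
  expect_identical(back$echo1, sim$echo1)
  expect_identical(back$echo2, sim$echo2)
  expect_equal(back$acq, acq)
  expect_error(read_dual_echo(file.path(tempdir(), "nope")), "missing echo")
})

test_that("phantom geometry is validated", {
  acq <- phantom_acquisition("fast")
  bad <- phantom_tissues("fast")
  bad$soleus$origin <- c(35, 35)  # rectangle would overflow the matrix
  expect_error(generate_dual_echo(acq, exercise_paradigm(), bad,
                                  ground_truth(), noise_spec("none")),
               "exceeds the matrix bounds")
  over <- phantom_tissues("fast")
  over$lateral_gastrocnemius$origin <- over$medial_gastrocnemius$origin
  expect_error(generate_dual_echo(acq, exercise_paradigm(), over,
                                  ground_truth(), noise_spec("none")),
               "overlaps")
  expect_error(noise_spec("rician", sigma = -1), "sigma")
})
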