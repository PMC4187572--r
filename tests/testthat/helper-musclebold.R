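# shared fixtures: everything is generated in code at test time


# a small fully synthetic dual-echo series with hand-set arrays, for tests
# that need direct control of the voxel values
tiny_series <- function(e1, e2, acq, paradigm = exercise_paradigm()) {
  structure(list(echo1 = e1, echo2 = e2, acq = acq, paradigm = paradigm),
            class = "dual_echo_series")
}

# noiseless fast-preset simulation with the default injected dynamics
fast_noiseless <- function(truth = ground_truth()) {
  generate_dual_echo(phantom_acquisition("fast"), exercise_paradigm(),
                     phantom_tissues("fast"), truth, noise_spec("none"))
}

# pipeline maximal-change estimate for one muscle ROI on a seeded noisy
# fast-preset dataset
fast_noisy_estimate <- function(truth, roi, seed, snr = 50) {
  res <- run_pipeline(pipeline_config(preset = "fast", seed = seed,
                                      truth = truth,
                                      noise = noise_spec("rician", snr = snr)))
  res$metrics$maximal_change[res$metrics$muscle == roi]
}
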