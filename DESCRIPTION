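Package: musclebold
Title: Quantitative Muscle BOLD fMRI Analysis of Dual-Echo R2* Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for blood-oxygenation-level-dependent (BOLD)
    functional MRI of exercising skeletal muscle. Converts dual-echo
    gradient-echo EPI time series to effective transverse relaxation rate
    (R2*) maps, extracts region-of-interest time courses for the calf
    muscles (soleus, medial and lateral gastrocnemius), computes
    cycle-averaged percent-change responses to a block-design plantar
    flexion paradigm, fits mono-exponential post-exercise recovery curves,
    and derives tissue-oxygenation maximal-change and recovery-change
    metrics with repeated-measures visit statistics. Includes a synthetic
    dual-echo calf phantom generator with injectable oxygenation dynamics
    and Rician noise for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    RNifti,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    nortest,
    optparse,
    withr,
    jsonlite
Config/testthat/edition: 3
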