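# musclebold

Quantitative analysis of muscle BOLD (blood-oxygenation-level-dependent)
functional MRI. During plantar flexion exercise, oxygen extraction in the
calf outpaces delivery; the resulting rise in deoxyhemoglobin raises the
effective transverse relaxation rate R2\* = 1/T2\*. `musclebold` turns
dual-gradient-echo EPI time series into per-muscle tissue-oxygenation
metrics and visit-comparison statistics. It is written for researchers
running exercise-challenge muscle fMRI studies (e.g. nitrate or vascular
interventions) who need a tested, reproducible estimation chain — and a
synthetic phantom to validate it against known ground truth.

## The method

With two echoes per excitation (TE1/TE2 = 21/60 ms, TR = 3 s), the
monoexponential decay `S(TE, t) = S0 · exp(−TE · R2*(t))` gives R2\* in
closed form per voxel and frame:

    R2*(t) = ln( S(TE1, t) / S(TE2, t) ) / (TE2 − TE1)

The pipeline then:

1. spatially smooths each echo volume (Gaussian, FWHM 3 × 3 × 6 mm,
   reflect boundaries);
2. computes R2\* maps with whole-run validity masking;
3. extracts ROI-mean time courses for soleus and the medial, lateral and
   combined gastrocnemius (rectangular ROIs on the middle six slices);
4. normalises to the `[15, 30)` s baseline and averages the final three
   of four 210 s exercise cycles (90 s contraction + 120 s recovery);
5. fits the post-exercise recovery with a single exponential
   `y(t) = plateau + (peak − plateau)·exp(−t/τ)` and extracts
   **maximal change** (peak amplitude of the cycle-averaged
   percent-change course) and **recovery change** (peak minus the fitted
   end-of-recovery value), plus τ;
6. compares visits with paired t-tests, one-way repeated-measures ANOVA,
   KS normality checks, and Pearson correlations of metric changes
   against blood-pressure changes.

A synthetic dual-echo calf phantom (`generate_dual_echo()`) with
injectable per-muscle dynamics and seeded Rician noise makes every stage
testable without any acquisition; noiseless generation followed by the
full pipeline returns the injected parameters to numerical precision.

## Worked example

Simulate a reduced-size phantom run at SNR 50 (soleus amplitude injected
at 5.12% of baseline R2\*, gastrocnemius at 6.04%, recovery τ = 40 s)
and analyse it end to end:

```r
library(musclebold)
cfg <- pipeline_config(preset = "fast", seed = 1,
                       noise = noise_spec("rician", snr = 50))
res <- run_pipeline(cfg)
res$metrics[, c("muscle", "baseline_r2star", "maximal_change",
                "recovery_change", "tau", "converged")]
#>                  muscle baseline_r2star maximal_change recovery_change   tau converged
#> 1  medial_gastrocnemius           29.97          6.056           2.818 37.80      TRUE
#> 2 lateral_gastrocnemius           30.08          5.685           2.886 56.81      TRUE
#> 3         gastrocnemius           30.01          5.932           2.836 42.45      TRUE
#> 4                soleus           30.00          5.162           2.542 38.06      TRUE
```

Reading the output: baselines recover the phantom's 30 s⁻¹ muscle R2\*;
the soleus maximal change of 5.16% sits within noise of the injected
5.12%; the recovery change ≈ D·(1 − e^(−120/τ)) with D = A/2; and τ is
estimated near the injected 40 s (smaller ROIs, like the lateral head,
are noisier). `run_pipeline()` can also persist NIfTI intermediates,
tidy CSV metrics and a full provenance record (`out_dir = ...`).

The `analysis/` directory holds the narrative workflow: `01_simulate.R`
(full-resolution dataset), `02_single_run_metrics.R` (recovered vs
injected metrics), `03_cohort_simulation.R` (a 9-subject × 3-visit ×
2-workload image-level cohort) and `04_group_stats.R` (visit-comparison
and BP-correlation tables), writing to `results/`.

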