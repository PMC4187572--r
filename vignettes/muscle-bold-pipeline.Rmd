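---
title: "Quantitative muscle BOLD fMRI: model, pipeline and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative muscle BOLD fMRI: model, pipeline and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(musclebold)
```

## The measurement

During plantar flexion exercise, working calf muscle extracts oxygen
faster than the vasculature replenishes it. Deoxyhemoglobin is
paramagnetic, so falling tissue oxygenation shortens T2\* and raises the
effective transverse relaxation rate R2\* = 1/T2\* — the
blood-oxygenation-level-dependent (BOLD) effect. A dual-gradient-echo EPI
sequence samples each imaging volume at two echo times, TE1 = 21 ms and
TE2 = 60 ms, every TR = 3 s. Under monoexponential decay,

$$S(TE, t) = S_0 \, e^{-TE \cdot R_2^*(t)},$$

two echoes determine R2\* in closed form:

$$R_2^*(t) = \frac{\ln S(TE_1, t) - \ln S(TE_2, t)}{TE_2 - TE_1}.$$

This two-point log-ratio is the unique two-echo solution of the decay
model; it is invariant to any common gain factor (coil sensitivity) and
is implemented in `r2star_from_dual_echo()`. Signals at or below a
positivity threshold (default `1e-6` times the median signal, a guard for
the logarithm) flag the voxel invalid. Masking is whole-run: a voxel
invalid at any frame is dropped from all frames, so ROI time courses
never have holes — the simplest contract for downstream curve fitting.
R2\* also carries a T2 contribution; no T2/T2\* decomposition is
attempted, and exercise-induced T2 changes would if anything reinforce
the direction of the reported effects.

## Exercise paradigm and time-course reduction

The block design is 60 s rest followed by four identical 210 s cycles of
90 s contraction (0.3 Hz) + 120 s recovery — 900 s, i.e. 300 frames at
TR 3 s. Frames are timestamped at acquisition onset (`t = i * TR`; the
standard protocol places every block boundary exactly on the frame
grid since 60 and 210 are multiples of 3), and all phase windows are
half-open `[start, end)` so each frame belongs to exactly one phase.
Slice-timing offsets are ignored.

Reduction per muscle ROI:

1. **ROI mean.** Rectangular per-slice ROIs replicated over the middle
   six of ten slices (the only symmetric choice): medial gastrocnemius
   32 × 6, lateral 16 × 6, soleus 25 × 6 voxels; the combined
   gastrocnemius is their 48 × 6 union, so its mean is the 2:1
   voxel-weighted mean of the heads.
2. **Baseline.** Mean over frames with onset in `[15, 30)` s — frames
   5–9 at TR 3 s. The half-open convention is a recorded constant; the
   first 15 s are discarded as equilibration.
3. **Percent change.** `(R2* − baseline) / baseline × 100`.
   Deoxygenation raises R2\*, so exercise produces a positive excursion.
4. **Cycle average.** Elementwise mean of the final three cycles aligned
   at cycle start. The first cycle is discarded as a muscle-memory
   transient. Averaging uses the single run-level baseline, so percent
   change and cycle averaging commute.

## Recovery model and metrics

The post-exercise portion of the cycle-averaged percent-change course is
fitted with a single exponential,

$$y(t) = \text{plateau} + (\text{peak} - \text{plateau})\,
e^{-t/\tau}, \qquad t = \text{time since end of exercise},$$

by Levenberg–Marquardt least squares (`minpack.lm::nlsLM`). The fit is
deterministic: `peak0` = first recovery frame, `plateau0` = mean of the
final 15 s, `tau0` = 30 s, with `tau` constrained to (0.1, 600] s. A
`tau` on the upper bound means the window carries no curvature
information and the fit is flagged rather than trusted; a flat segment
is flagged degenerate (`tau` unidentifiable, amplitude 0). Flags
propagate into the metrics — nothing is fabricated from a failed fit.

Two headline metrics per muscle and run:

* **Maximal change** — the peak amplitude: the maximum of the
  cycle-averaged percent-change series (first occurrence on ties).
* **Recovery change** — maximal change minus the *trough*, where the
  trough is the fitted model value at the end of the 120 s recovery
  window. Using the fitted value rather than the raw minimum reflects
  that fitting precedes extraction and suppresses single-frame noise; a
  `raw_trough` flag restores the raw-minimum variant. "Normalised by
  peak amplitude" is ambiguous between a difference in
  percent-of-baseline units and that difference divided by the peak;
  published recovery-change magnitudes are consistent with the former,
  so the unnormalised difference is the default and
  `recovery_change_normalized` reports the divided form alongside.
  Signed values are preserved (a trough overshoot makes the normalised
  form negative).

## The synthetic phantom

No subject-level data accompany the study design this package
implements, so validation rests on a generator with injectable,
recoverable ground truth. The phantom is a calf cross-section: disjoint
rectangles for soleus and the two gastrocnemius heads (all R2\* =
30 s⁻¹, S0 = 1000) over background (R2\* = 25 s⁻¹, S0 = 500, a 2:1
proton-density contrast). These tissue constants are fixed, arbitrary
but physiologically plausible values; no published values exist for
them. Muscle rectangles extend beyond the analysis ROIs by at least the
smoothing-kernel radius, emulating the conservative manual ROI placement
away from muscle borders (done with angiographic reference in practice),
so smoothing never mixes background into an ROI.

Each muscle's injected percent-change profile is: 0 during baseline; a
linear ramp to the peak amplitude A during each 90 s exercise block; and
$(A - D) + D e^{-t/\tau}$ during recovery, with D the recovered amount
and τ = 40 s by default. The true on-exercise shape is not knowable from
published figures, which are only illustrative; the ramp is the simplest
shape with an unambiguous peak at the exercise→recovery boundary, and
the profile function is pluggable. Cycles after the first start from the
previous cycle's end value, making the profile cycle-periodic from cycle
2 — consistent with the analysis discarding cycle 1. Default amplitudes
(soleus 5.12%, gastrocnemius 6.04%, D = A/2) are representative of the
15% MVC workload under control conditions.

Noise is Rician — the magnitude-image distribution,
$\sqrt{(S+n_1)^2 + n_2^2}$ with independent Gaussian $n_1, n_2$ per
echo, frame and voxel. **SNR convention:** SNR = (first-echo muscle
baseline signal) / σ, the standard magnitude-image convention referenced
to the shortest echo; SNR 50 gives σ ≈ 10.7 here. At high SNR the
Rician mean is inflated by ≈ σ²/(2S); at SNR 50 the resulting
differential R2\* bias between baseline and peak is below 0.02
percentage points, negligible against fit tolerances. Generation is
seed-deterministic and leaves the caller's RNG state untouched.

Two geometries: the full-resolution preset (80 × 80, 2.5 mm in-plane)
and a reduced 40 × 40 preset (same 200 mm FOV, 5 mm in-plane voxels,
ROI rectangles halved) used for simulation studies where many datasets
are needed; validation uses 20 seeded datasets per condition and a
50-dataset parameter-recovery check, sizes chosen to estimate
across-seed means to ≈ 0.05 pp precision.

What the phantom does **not** emulate: subject motion (inputs are
assumed motion-corrected upstream; the reference workflow used a
standard realignment package), large vessels and adipose fat inside
ROIs, EPI distortion and B0 inhomogeneity, physiological signal
fluctuations, partial-volume gradients at muscle borders, and any
mechanistic blood-flow/volume coupling. Passing tests therefore
demonstrate correctness of the estimation chain under the stated signal
and noise model, not robustness to those real-data effects.

## Spatial smoothing

Volumes are smoothed per frame and per echo (before the R2\*
log-ratio, matching a workflow that smooths raw images before
time-course extraction) with a separable Gaussian of FWHM 3 × 3 × 6 mm
(σ = FWHM / (2√(2 ln 2)) / voxel). Boundary handling is
reflection, which preserves kernel mass (no DC shift). Per-echo
smoothing is the only order consistent with computing R2\* afterwards.
Smoothing is exactly linear and frame-independent; on the phantom,
where ROIs sit inside uniform tissue, it leaves noiseless ROI means
unchanged. Note that for ROI-*mean* statistics smoothing mostly
redistributes noise within the ROI rather than removing it: the ROI
mean's variance is set by σ_voxel/√N, not by the kernel.

## Statistics

Visit comparisons operate on per-subject metric tables: classical
paired t-tests per visit pair and one-way repeated-measures ANOVA
across visits (`df1 = k−1`, `df2 = (k−1)(n−1)`; for two visits
F = t² exactly). Normality is checked with a one-sample
Kolmogorov–Smirnov test against a normal with the sample's mean and SD;
estimating the parameters from the sample makes this conservative
(the Lilliefors correction is available as an option). Correlations
between visit-to-visit metric changes and blood-pressure changes use
Pearson r with the exact t transform
`t = r√(n−2)/√(1−r²)`. Complete-case pairing is used per comparison,
and no multiple-testing correction is applied (pre-defined comparisons
at α = 0.05, stated in the output rather than adjusted). One boundary
convention: identical paired vectors return t = 0, p = 1 (no evidence
of a shift) rather than erroring, while constant non-zero differences —
where the statistic is genuinely undefined — raise an error.

Screening follows the cohort rules: MVC inside 200–700 N (endpoints
eligible) and IPAQ ≤ 10,000 MET-min; resting BP is the mean of the
second and third of three supine readings.

## Known limitations

* **Peak-statistic noise bias.** The maximal change is the maximum of a
  noisy series, which is biased upward; the bias grows as the injected
  amplitude shrinks because the ramp and the slow (τ = 40 s) early
  recovery leave several frames within noise range of the peak. At
  SNR 50 on the reduced phantom the across-seed mean overshoots a
  2.55% amplitude by ≈ 0.2 pp (and a 5.12% soleus amplitude by
  ≈ 0.15 pp), as the validation suite records; the combined
  gastrocnemius ROI, with twice the voxels, keeps the bias below
  0.1 pp. A fitted-peak estimator would trade this bias for model
  dependence and is deliberately not the default.
* Whole-run masking discards a voxel for one bad frame; appropriate for
  clean simulated data, aggressive for data with transient dropouts.
* The generator's ramp-plus-exponential profile is an idealisation; all
  closed-form oracle values inherit it.
* The recovery fit assumes the 120 s window contains meaningful
  curvature; τ approaching the window length is flagged rather than
  estimated.
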