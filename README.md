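# whisktouch

Spike-train analysis of active whisker touch for single-unit recordings
from the barrel cortex, plus a calibrated synthetic-session generator
with per-spike ground truth.

Mice localizing an object with a single whisker generate their own
tactile input: they whisk in bouts and touch the pole a few times per
trial, and layer-4 neurons in the matching barrel fire almost
exclusively in millisecond windows after touch onset.  Analyzing such
recordings requires aligning sparse spikes to fine-scale behavior.
This package implements that pipeline:

- **Kinematics** — bandpass (6–60 Hz Butterworth, zero-phase) and
  analytic-signal decomposition of whisker angle into whisking phase
  φ and amplitude; segmentation into whisking / non-whisking /
  exploration epochs; per-touch features (order, pretouch velocity,
  max |Δκ|, inter-contact interval).
- **Spike metrics** — touch-aligned PSTHs, onset latency (first 1-ms
  bin exceeding the pre-touch mean by 2 s.d.), occupancy-normalized
  12-bin phase histograms with the cosine fit
  `A[1 + cos(φ − φ_pref)] + B` (A, B ≥ 0) and modulation depth
  `A/(A+B)`, epoch firing rates and minimum ISI.
- **Attribution** — the fraction of exploration-epoch spikes coupled
  to touch onset, and of the residual to whisking phase, from
  cumulative explained-spike curves with shuffle-based chance slopes
  (1000 shuffles, degree-11 polynomial smoothing, 95th-percentile
  cutoff).
- **Touch tuning** — mean spikes/touch across 10 equal-occupancy
  feature bins with bootstrap CIs and the modulation index
  `(max − min)/(max + min)`.
- **Spike-count variability** — Fano factors (`variance/mean`), the
  binomial minimum bound `1 − mean` (mean < 1) with a brute-force
  verifier, ICI-filtered touch selection, density-based grouping of
  similar touches (OPTICS ordering + minimal-pairwise-distance window
  scan), sliding-window Fano curves, refractory-Poisson nulls, and
  the five-condition alignment comparison.
- **Decoding** — resampling-based population simulations: touch
  detection by a thresholded pooled count, time-since-touch by
  multinomial naive Bayes (RMS error), and whisking-phase
  discrimination at the d′ = 1 criterion (76% correct,
  `Φ(1/√2)`).

The synthetic generator emulates the study conditions (261 ms mean
bout duration, 15.7° peak-to-peak amplitude, 15.4 Hz whisking, 2.33
touches/trial, ~0.7 spikes per touch at 8 ms latency, cosine phase
tuning) and labels every spike as touch-evoked, phase-coupled or
baseline, so estimator accuracy is tested against known truth.

## Worked example

```r
library(whisktouch)

cfg <- generator_config(n_trials = 100, seed = 42)
session <- generate_session(cfg)
res <- run_pipeline(session, pipeline_config(seed = 1))
print(res)
#> pipeline_result
#>   trials 100, touches 236, spikes 341
#>   latency 8 ms, depth 0.38, frac_touch 0.67, min FF 0.19
unlist(res$summary[c("frac_touch", "ff_condition_1", "ff_condition_4")])
#>     frac_touch ff_condition_1 ff_condition_4
#>       0.672000       1.618507       0.281245
```

Reading the numbers: the cell's onset latency is 8 ms; 67% of its
exploration-epoch spikes fall inside the touch windows found by the
attribution step (the generative truth for this seed is 69%);
counting spikes over the whole sample period gives a Fano factor of
1.62, driven by trial-to-trial behavioral variability, while the
minimum 10-ms sliding-window FF after touch is 0.28 — essentially the
binomial limit `1 − 0.7` for this cell's 0.7 spikes/touch, i.e. the
response is as reliable as integer spike counts allow.  The fitted
modulation depth (0.38 here) is a noisy estimate of the generative 0.5
at this session length; the recovery tests average it over longer
sessions.

Sessions round-trip through plain files (`write_session()` /
`read_session()`: CSV tables plus a JSON manifest), and each pipeline
stage is exported on its own (`decompose_whisking()`,
`touch_coupled_fraction()`, `sliding_fano()`, `decode_phase()`, ...).

## Vignette

`vignettes/whisktouch-methods.Rmd` documents the generative model and
its calibration, every threshold and convention in the pipeline
(phase origin, epoch rules, cutoff smoothing, variance estimators,
OPTICS parameters, decoder losses), and the known limitations.
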