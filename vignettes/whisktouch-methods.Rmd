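---
title: "Models and methods behind whisktouch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind whisktouch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(whisktouch)
```

# The scientific setting

Head-fixed mice localize a pole with a single whisker.  The behavioral
substrate is the whisker's azimuthal angle $\theta(t)$ (degrees) and
curvature $\kappa(t)$ (1/mm), sampled at 1 kHz, with annotated touch
intervals, lick times and the pole-in-reach (sample) epoch.  Layer-4
excitatory neurons in the corresponding barrel fire sparsely, and most
of their spikes occur within milliseconds of touch onset.  The package
quantifies that coupling: how spikes distribute over touch and whisking
phase, how strongly touch responses are modulated by stimulus features,
how little their spike counts vary across comparable touches, and how
well small populations could decode touch events.

Every analysis is exercised end-to-end on a synthetic-session generator
with per-spike ground truth, so all the parameter-recovery claims in
the test suite are checked against known truth rather than against a
fixed dataset.

# The synthetic-session generator

`generator_config()` / `generate_session()` implement a generative
model of one recorded cell in one behavioral session.

**Whisking.**  $\theta(t)$ is a slow sinusoidal setpoint plus
bout-gated oscillation.  Bout durations are gamma (mean 261 ms, shape
4) — the gamma gives positivity and a realistic spread around the
reported mean — separated by exponential pauses (mean 220 ms, which
sets a duty cycle reproducing roughly 1.3 s of in-reach whisking per
2.4 s sample epoch).  Within a bout the instantaneous frequency is
redrawn each cycle (normal, mean 15.4 Hz, s.d. 2 Hz) and the
peak-to-peak amplitude is drawn per bout (normal, mean 15.7°, s.d. 2°)
with raised-cosine ramps of 20 ms at each end.  Two small calibration
details matter: the drawn bout duration is interpreted as the time the
envelope exceeds the 1.25° quiet threshold (the sub-threshold ramp
time is added analytically), and the drawn amplitude is shrunk by 2%
to compensate for bandpass edge overshoot in the measurement pipeline.
With those corrections the *measured* bout statistics of generated
sessions match the configured targets; the ramp length (20 ms) was
itself calibrated so that cycle-length statistics measured through the
Hilbert pipeline average to the configured frequency (edge cycles bias
the naive mean otherwise).

**Touches.**  Touch onsets are placed just before protraction peaks
(uniform 0–15 ms lead, giving positive pretouch velocities) while the
pole is in reach, thinned so the expected count per trial is 2.33.  A
gamma-distributed per-trial propensity (shape 1.5) overdisperses touch
counts across trials, emulating the broad empirical distribution; this
matters for the coarse Fano-factor condition, which feeds on
trial-to-trial behavioral variability.  Touch durations are gamma
(mean 45 ms) so that a few percent exceed 100 ms and exercise the
prolonged-touch exclusion.  Each touch adds a curvature transient:
linear rise over 10 ms, plateau, exponential release (only the maximum
|Δκ| within 0–20 ms matters downstream, so the shape is otherwise
free).

**Spikes.**  Three labelled processes: (i) touch-evoked spikes, one
Bernoulli draw per touch (probability 0.7 by default; a Poisson count
model is available) at latency 8 ms plus gamma-distributed jitter
(shape 2, s.d. 1 ms) — gamma rather than normal because sensory
latencies have a conduction-delay floor and a right-skewed tail, which
also keeps the measured onset latency at the configured value; (ii)
phase-coupled spikes from an inhomogeneous Poisson process with rate
$A[1+\cos(\phi-\phi_{pref})]+B$ during whisking (defaults $A=B=0.26$
spikes/s, i.e. modulation depth 0.5); (iii) a homogeneous baseline
(0.02 spikes/s).  Spikes closer than 2.3 ms to their predecessor are
deleted (forward deletion, earlier spike kept), matching the
refractory construction used by the Poisson null.  The defaults are
balanced so that about 70% of exploration-epoch spikes are
touch-evoked.  A log-linear link (off by default) can modulate the
per-touch probability by touch order, pretouch velocity and |Δκ|.

**What the generator does not emulate:** across-neuron noise
correlations (the decoding module inherits the independence
assumption), biophysical whisker mechanics, multi-whisker
interactions, slow nonstationarities in excitability, and tuning
shapes sharper than a cosine.  Tests passing on synthetic data
demonstrate that the estimators recover the generative parameters
under these idealizations, not that real L4 data satisfy them.

# Kinematics

`decompose_whisking()` bandpasses $\theta$ to 6–60 Hz with a
fourth-order Butterworth filter applied forward and backward
(zero-phase, so spike times and phase stay aligned) and takes the
analytic signal.  Phase convention: $\phi = 0$ at maximum protraction,
$\pm\pi$ at maximum retraction; whisk cycles span $-\pi \to \pi$ and
are delimited at the wrap.  Cycles with non-monotonic unwrapped phase
are flagged and excluded from phase analyses but kept for the
phase-window attribution step.

`segment_epochs()` applies the threshold rules: a cycle is *whisking*
when its peak-to-peak bandpassed amplitude exceeds 2.5° (we read the
2.5° threshold as peak-to-peak, equivalently envelope above 1.25°,
which reconciles it with the 1.25° quiet threshold); *non-whisking*
epochs are runs of at least 100 ms with envelope below 1.25° and no
touch or lick; cycles during licking or within 70 ms after a touch are
flagged unusable for phase tuning; *exploration* is whisking plus
touches (touches longer than 100 ms removed) inside the pole-in-reach
period.  Whisking epochs are additionally trimmed to samples with
envelope at or above 1.25°, because in quiet periods the phase of
near-zero noise wraps slowly and a nominal "cycle" can leak far
outside the bout; the trim also makes whisking and non-whisking
disjoint by construction.  All intervals are half-open `[start, end)`
in ms; an event on a boundary belongs to the later interval.

Per-touch features (`extract_touch_features()`): pretouch velocity is
the least-squares slope of $\theta$ over the 5 ms ending at onset (the
window length is our choice; "velocity at touch onset" needs one);
max |Δκ| is taken over 0–20 ms after onset against the median
$\kappa$ of the 10 ms before onset; the inter-contact interval is
measured from the previous touch *offset*.

# Spike metrics

`touch_aligned_psth()` counts spikes around first-touch or all-touch
onsets.  `onset_latency()` finds the first post-onset 1-ms bin whose
rate exceeds the pre-touch mean (−50 to 0 ms) by two pre-touch
standard deviations; because silent baselines have zero mean and zero
s.d., the bin must also contain at least one spike, so a single spike
can trigger onset in a silent cell but an empty bin never can.  The
search is capped at +50 ms.

`phase_tuning()` builds the 12-bin, occupancy-normalized phase
histogram (spikes per second of dwell time per phase bin, pooled over
usable cycles before normalizing — pooling first keeps empty cycles
from producing unstable per-cycle rates) and fits
$A[1+\cos(\phi-\phi_{pref})]+B$ with $A,B\ge 0$ by occupancy-weighted
least squares.  The fit runs a 72-point grid over $\phi_{pref}$ (each
grid point is a 2-parameter nonnegative linear solve) followed by a
local continuous refinement, which avoids the local minima a single
nonlinear start can fall into.  Modulation depth is $A/(A+B)$, in
[0, 1] by construction.  Note one small bias worth knowing about: any
untuned baseline firing during whisking is absorbed into $B$, so the
fitted depth of a cell whose tuned component has depth 0.5 sits
slightly below 0.5 (about 0.02 at the generator defaults).

# Spike attribution

`touch_coupled_fraction()` indexes every exploration-epoch spike by
the time since the most recent touch onset of its trial minus the
cell's onset latency (windows are post-onset only: a spike cannot be
attributed to a touch that has not happened).  The cumulative count
$y(t)$ over expanding 1-ms windows rises steeply while windows collect
genuine touch responses and then grows at the chance rate.  Chance is
estimated from 1000 shuffles that redistribute each trial's
exploration spikes uniformly over that trial's exploration epochs
(count-preserving, timing-destroying, and supported exactly on the
analysis domain); each surrogate cumulative curve is smoothed with a
degree-11 polynomial (fit on a grid rescaled to $[-1,1]$ for
conditioning) and differentiated, and the chance slope is the 95th
percentile over surrogates at each window size.  The empirical curve
receives the *same* smoothing before differentiation: comparing a raw
1-ms increment (a small Poisson count) against a smoothed chance
slope terminates spuriously early at realistic spike counts, whereas
smoothing both sides compares like with like.  The cutoff $t_{on}$ is
the first window whose smoothed slope drops below chance;
`frac_touch` is $y(t_{on})$ over the exploration spike count.

`phase_coupled_fraction()` repeats the construction for the residual
spikes, indexing each spike inside a whisk cycle by its distance to
the nearest preferred-phase crossing of *that* cycle (windows truncate
at cycle margins; non-monotonic cycles contribute every crossing).
Spikes in both a touch and a phase window count once, for touch —
touch is attributed first and only the residual enters the phase step.
The phase step is conservative: cosine tuning concentrates spikes at
most twofold over chance near the preferred phase, so a small phase
component can legitimately remain below the 95th-percentile chance
slope and go unattributed.

# Touch-response tuning

`bin_touch_responses()` sorts touches by a feature and splits them
into 10 bins with equal counts (±1; ties keep chronological order via
the stable sort).  Per-bin means get percentile bootstrap CIs (1000
resamples).  The modulation index is (max − min)/(max + min) over bin
means, scale-invariant and in [0, 1].  The per-touch count window is
the cell's own touch window from the attribution step
(`[latency, latency + t_on)`), falling back to `[8, 38)` ms when
attribution has not been run.

# Spike-count variability

`fano_factor()` uses the population (1/n) variance by default — the
minimum-FF bound is exact for the empirical distribution under this
estimator, so data can approach but never beat the bound — with the
sample estimator available.  `min_fano()` is the closed form
$(\mu-k)(k+1-\mu)/\mu$, $k=\lfloor\mu\rfloor$ (equal to $1-\mu$ below
1); `min_fano_brute()` verifies it by enumerating the two-point
supports that are the vertices of the underlying linear program.

Touch grouping (`group_touches()`): touches surviving the strict
ICI > 250 ms filter are z-scored on (pretouch velocity, max |Δκ|) and
grouped by running OPTICS (implemented in-package; Euclidean distance,
`min_pts = 10`, unlimited reachability radius — `min_pts` is not
stated by the grouping procedure we follow, so it is small relative to
the group size and configurable), scanning every window of $N$
consecutive points in the OPTICS order for the minimal total pairwise
distance, removing the winner, and repeating five times.  $N$ is 20%
of the remaining touches, floored at 20.

`sliding_fano()` computes FF in 10-ms windows at offsets 0–20 ms after
onset, per group and pooled, with bootstrap CIs and the binomial
bound.  `refractory_poisson_null()` simulates an inhomogeneous Poisson
process from the cell's PSTH with forward refractory deletion — the
natural null for "is the low FF just refractoriness?".
`ff_conditions()` assembles the five-alignment comparison: sample
period; random 38-ms windows in the sample period matched per trial to
the touch count (drawn uniformly, overlap allowed); 38-ms windows at
onset + 6 ms; the pooled minimum sliding FF; and the mean over the
five groups' minimum sliding FFs.  Minima over offsets are
noise-biased downward, which is why the two minimum-based conditions
sit below condition 3 even for a feature-independent generator; with
feature-dependent responses the grouping removes real stimulus
variance as intended.

# Population decoding

Populations are resampled: neurons are drawn with replacement (so
populations larger than the recorded set are well-defined) and each
neuron contributes 1000 resampled touch-aligned responses, causally
integrated over 10 ms, on a −30 to +50 ms grid.  Touches followed by
another touch within 50 ms are excluded.  Non-touch counts come from
exploration windows at least 100 ms from any touch (the buffer is our
choice and configurable).

*Presence*: at each time point a threshold on the pooled count is
trained on half the draws by maximizing balanced accuracy (the loss is
unstated in the procedure we follow; balanced accuracy keeps the
threshold honest under class imbalance) and evaluated on the held-out
half.  *Time since touch*: a multinomial naive Bayes classifier over
time-point classes, count likelihoods estimated with add-one
smoothing, RMS error bootstrapped over 100 runs.  *Phase*: per-neuron
responses binned into 120 phase bins, preferred phases uniformized by
random circular shifts, and a Poisson naive Bayes log-likelihood ratio
discriminates $\phi$ from $\phi+\Delta$; the reported resolution is
the smallest $\Delta$ reaching 76% correct, the two-alternative
equivalent of $d'=1$ ($\Phi(1/\sqrt 2) = 0.76$).  Ties in the
likelihood ratio (e.g. zero pooled spikes) are broken by a fair coin,
which pins untuned populations at exactly chance.

# Numerical conventions and degenerate inputs

Times are ms floats at 1 µs precision; all intervals half-open;
events on a boundary belong to the later interval.  Every stochastic
routine takes a `seed` and restores the caller's RNG state; a session
is a pure function of its configuration.  Degenerate inputs are
flagged rather than silently propagated: zero whisking time errors,
zero spikes warn and return `NA` depth, zero-mean counts warn and
return `NA` FF, a latency that never triggers returns `NA` and the
attribution step then runs from latency 0.

The test suite runs the recovery analyses at problem sizes chosen to
make the tolerances meaningful at tolerable runtime: six synthetic
cells of 350 trials (roughly 800 touches and eight minutes of usable
whisking each) for parameter recovery, 100 20-trial sessions for the
chance-band null, and 20 cells of 80 trials for the condition
ordering.

# Known limitations

The cosine is the only tuning shape the generator and the fit speak;
real cells are often sharper, which mainly affects the phase
attribution (conservative here) and phase decoding (pessimistic
here).  The whisking-epoch firing rate includes touch-evoked spikes
when touches occur mid-bout, so it overstates the movement-related
rate for strongly touch-driven cells.  OPTICS hyperparameters are
fixed defaults, not tuned per cell.  Decoding assumes independent
neurons throughout.
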