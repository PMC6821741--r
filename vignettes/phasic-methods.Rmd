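---
title: "Models and methods behind phasic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phasic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

phasic implements a pair of complementary analyses for experiments in
which listeners hear rapid sequences of short (750 ms) auditory snippets
belonging to two conditions — canonically a *familiar* (condition A) and
an *unfamiliar* (condition B) song — while pupil diameter and EEG are
recorded. This vignette explains the statistical models, the tunable
parameters, what the synthetic-data generator does and does not emulate,
and the numerical and design choices that are not forced by the problem
itself.

## Pupil dilation-event rate

### From diameter to events

Averaging pupil diameter over trials is dominated by slow dynamics
(seconds), too sluggish for a paradigm with a new stimulus every ~2 s.
The event-rate analysis instead treats the pupil trace as a point
process: a *dilation event* is a sample at which the diameter starts to
rise, defined through the first difference `d[i] = x[i+1] - x[i]` as any
sample with `d[i] > 0` and `d[i-1] <= 0`. Two consequences of this
definition are deliberate:

* A flat trough produces exactly one event, at its first rising sample
  ("begins to increase").
* The derivative is instantaneous — no pre-smoothing by default. A
  moving-average `presmooth_ms` parameter exists for noisier hardware,
  but the default of 0 keeps the definition literal.

Samples whose gaze position is more than 1° from fixation (radial
deviation) are invalidated beforehand; the derivative is undefined
across invalid gaps, so no event can be created by the excision itself,
and events on invalid samples are discarded.

### From events to a rate

Per trial, events inside the half-open peristimulus window
`[-500, 1500)` ms are binned into binary impulse trains on the sampling
grid, summed across trials, and scaled by `fs / n_trials`, which makes
the units events/second before any smoothing. The rate is then smoothed
with the causal gamma-shaped kernel

&omega;(&tau;) = &alpha;&sup2; &tau; e^(&minus;&alpha;&tau;), &tau; &ge; 0,

the same family used for spike-train firing-rate estimation. Its
integral is exactly 1 — so a stationary Poisson input of rate &lambda;
is mapped to a plateau at &lambda; — and its peak sits at
&tau; = 1/&alpha;. Defaults: &alpha; = 1/50 per ms (peak lag 50 ms,
mean lag 100 ms) and truncation at 500 ms, which leaves an integral
deficit of (1 + &alpha;T)e^(&minus;&alpha;T) &asymp; 5&times;10&#8315;&#8308;;
the kernel is *not* renormalised after truncation, the deficit is
reported instead. Finally the mean over the pre-onset baseline interval
`[-200, 0)` ms is subtracted. The window and baseline mirror the EEG
epoching; the choice is a convention, not an estimate.

Note that causality matters for interpretation: the smoothed rate at
time *t* depends only on events at or before *t*, so an onset of
significance cannot be driven by later events; it does mean the
response to an event spreads up to 500 ms *forward*, which is why an
effect injected at 100–300 ms also elevates the smoothed rate out to
roughly 800 ms.

### Group inference

For each subject the A−B difference rate series is formed. Significance
at each time point uses subject-level bootstrap resampling (default
1000 iterations): a point is significant when the proportion of
bootstrap across-subject means above zero *or* below zero exceeds the
criterion (default 0.99). Two properties of this rule deserve emphasis:

* The OR over tails makes its nominal two-sided level about
  2&times;(1&minus;criterion) = 2%, not 1%.
* The percentile bootstrap runs hot at small samples: in our null
  simulations the per-time-point rejection rate is ~5.7% at n = 10
  subjects and ~3.2% at n = 20. Combined with the kernel's
  autocorrelation (~200 ms), a 2 s epoch contains on the order of 10–15
  effectively independent points, so the probability of *some*
  significant interval somewhere in an epoch of pure noise is
  substantial (tens of percent). Users should treat isolated short
  intervals with caution and rely on the two built-in controls:
  trial-label shuffling within subject (destroys any true condition
  effect while preserving everything else) and the control-pool
  bootstrap (an H0 distribution built from datasets where both
  conditions are equivalent).

Significant intervals are maximal runs of consecutive significant
samples; a single sample counts as a run. Resampling p-values use the
add-one convention `(1 + #extreme) / (n_iter + 1)` and can therefore
never be exactly zero.

## EEG cluster-based permutation test

Preprocessing follows the conventional chain: anti-aliased decimation
to 128 Hz, zero-phase FIR low-pass at 40 Hz (order 64, Hamming design;
applied forward-backward so the effective attenuation doubles and phase
is exactly zero), average reference, epoching at `[-500, 1500)` ms and
baseline correction over `[-200, 0)` ms. There is deliberately no
high-pass filter, to preserve sustained low-frequency responses. Epoch
screening is automatic: six per-epoch summary statistics (variance,
range, maximum absolute value, mean and maximum absolute z-score,
kurtosis), each converted to a robust z-score across epochs
(median/MAD), with rejection when any statistic exceeds the threshold
(default 5). This replaces interactive visual screening and independent
component analysis; it removes gross artefacts only, and is declared as
such.

The test itself: a paired t-statistic at every (channel, time) sample;
samples with |t| above the two-sided critical value at `cluster_alpha`
(default 0.05) are grouped into connected components under spatial
channel adjacency (Euclidean distance threshold on the planar layout)
plus temporal succession, separately per sign; each cluster is scored
by its summed t (`T_sum`). The null distribution of max |T_sum| is
obtained by flipping each subject's condition sign — the exact
permutation scheme for a paired design — exhaustively over all 2^n
assignments when 2^n does not exceed `n_perm`, otherwise by seeded
Monte-Carlo draws (the observed assignment and its mirror are excluded
from Monte-Carlo draws; they constitute the observed statistic). A
cluster is significant when its add-one p-value is at most
`fwer_alpha` = 0.05, which controls family-wise error over the whole
channel × time search space. The cluster-forming threshold is a tuning
parameter that affects sensitivity, not validity; 0.05 two-sided is the
de-facto default in this literature and is exposed as `cluster_alpha`.

Follow-ups: the mean amplitude over a cluster's members per subject and
condition feeds a 2×2 mixed-design ANOVA (within factor: familiarity;
between factor: group), computed via `stats::aov` with a subject error
stratum; partial &eta;&sup2; is SS_effect/(SS_effect+SS_error) within
the effect's stratum. When a stratum carries (numerically) no variance
the F is reported as 0 rather than a 0/0 artefact. The dyad-matched
bootstrap assigns one random control subject per dyad on each of 1000
iterations and averages their condition differences over the region of
interest, giving an H0 distribution for the main group's observed mean.

## The synthetic-data generator

The generator exists so the full pipeline can be exercised and
calibrated with known ground truth; its defaults encode the paradigm's
stated structure:

* **Trial schedule** — 200 trials per block, 750 ms snippets, ISI
  uniform on [1000, 1500] ms, balanced 50/50 random condition labels.
  A block therefore lasts ~6.7 minutes.
* **Pupil model** — dilation events are an inhomogeneous Poisson
  process: baseline 2 events/s plus, after onsets of the matching
  condition, a raised-cosine rate bump (default onset 100 ms, width
  200 ms). Each event adds a gamma-shaped diameter transient whose
  amplitude (0.05 a.u.) and time-to-peak (80 ms) are parameterised
  independently of the analysis kernel, so detection is not circular.
  The 80 ms time constant was chosen because the event-based analysis
  presupposes that successive events produce discernible diameter
  minima: with transients much slower than the typical inter-event
  interval (~300–500 ms at these rates), a new event arrives while the
  previous transient still rises and leaves no local minimum to detect.
  Slow baseline wander (spline-interpolated Gaussian knots at ~1 s
  spacing, SD 0.01 a.u.) and contiguous gaze-excursion runs (>1°,
  geometric run lengths, mean 100 ms) exercise the drift- and
  gap-handling paths.
* **EEG model** — each epoch is a shared onset-response template
  (biphasic early peaks plus a sustained deflection), a subject-constant
  offset (SD 2 µV), i.i.d. Gaussian sensor noise (10 µV), and, for
  condition B, a constant shift confined to an
  `effect_channels × effect_window` block — the ground-truth cluster.
  Channels live on a near-square unit grid.

What the generator does *not* emulate — and what passing tests on it
therefore cannot show: real blink artefacts (gaze excursions stand in),
1/f and oscillatory EEG background with spatial covariance (noise is
white in space and time, so real-data cluster sizes will differ),
amplitude variability of pupil transients, and any dependence between
the pupil and EEG modalities.

In the recovery experiments we use a bump amplitude of 2 events/s —
i.e. a per-subject signal-to-noise ratio in a clearly detectable
regime for 100 trials/condition — because their purpose is to verify
that the pipeline finds what is there and loses it under label
shuffling, not to estimate a psychometric threshold.

## Numerical choices and degenerate inputs

* Convolutions are FFT-based, zero-padded to 5-smooth lengths; the
  causal output at index *i* uses inputs at indices &le; *i* only.
* Half-open intervals `[start, end)` everywhere, onset at 0, avoid
  double-counting boundary samples.
* Time grids are validated to 1 ppm relative step tolerance on file
  input.
* Empty event sets are valid everywhere (zero rate, no clusters is a
  valid test result); zero-variance behavioural scores report an
  infinite t rather than erroring.
* All resampling takes one master seed; iteration-level streams are
  drawn deterministically from it, so identical seeds and configuration
  give byte-identical outputs.

## Problem sizes used in the shipped experiments

The packaged tests and the acceptance script run: 200 simulated null
EEG studies (10 subjects, 16 channels, 50 samples, 500 permutations)
for the family-wise error-rate estimate; 50 replicate pupil studies
(10 subjects × 200 trials at 1000 Hz) for effect recovery and the
shuffle control; and 500-trial Poisson calibrations for the kernel's
rate-conservation property. These sizes give binomial/Monte-Carlo
standard errors comfortably below the margins being tested while
keeping a full run in the minutes range on one core.

## Known limitations

* The per-time-point bootstrap criterion is anticonservative at small
  n (see above); it is implemented as specified, with the shuffle and
  control-pool analyses as the intended guards.
* The epoch rejector targets gross outliers only; structured artefacts
  (line noise, slow drifts shared across epochs) pass through.
* The cluster test's spatial adjacency is a plain distance threshold;
  irregular montages may need a hand-curated neighbour structure.
* `preprocess_eeg` requires the input rate to be an integer multiple of
  the analysis rate (rational resampling is out of scope).
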