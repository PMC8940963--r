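---
title: "Methods: no-report rivalry analysis and its synthetic testbed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: no-report rivalry analysis and its synthetic testbed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models and conventions behind `okndecode`: what
each stage computes, the tunable parameters and their defaults, what the
synthetic-session generator does and does not emulate, and the numerical
choices made where a convention had to be fixed.

## The paradigm being analysed

Four trial types are supported. In **physical alternation (PA)** trials a
drifting grating is shown monocularly and physically swapped between the
eyes, so perceptual changes follow the stimulus. In **binocular rivalry
(BR)** trials an initial monocular phase (1–2 s) is followed by the
addition of an oppositely drifting stimulus to the other eye, which
typically suppresses the first one (**binocular flash suppression, BFS**,
the only exogenous event of the trial); thereafter perception alternates
endogenously. **Fixation-Off / Fixation-On** control trials present 1 s of
motion in one of eight directions with the OKN respectively elicited or
suppressed by a fixation requirement. Trials last 8–10 s (default 9 s);
eye position is sampled at 1 kHz, broadband voltage at 30 kHz.

Because no report is collected, the perceived direction during rivalry is
inferred from the OKN: slow pursuit phases drift with the perceived motion
and are interrupted by fast resetting saccades, so the *sign of the
slow-phase velocity* indexes the percept.

## Synthetic sessions

The generator (`synth_config()`, `generate_session()`) is a first-class,
tested component: it produces trials, events, spikes, eye traces and the
ground truth needed to validate every downstream stage.

* **Dominance durations** are gamma distributed (default shape 3, scale
  800 ms, i.e. mean 2.4 s — typical of primate rivalry). Draws below
  300 ms are resampled: dominances that short are excluded by every
  analysis rule (all selectivity and decoding windows require ≥ 1 s of
  dominance), so they would only shorten usable trials while exercising
  nothing.
* **OKN traces** are sawtooths: slow phases at `okn_slow_phase_speed`
  (12 °/s, the stimulus speed) in the perceived direction, instantaneous
  resets once the excursion reaches `okn_reset_threshold` (4°, keeping the
  trace well inside the ±8° fixation window), plus Gaussian positional
  noise (default SD 0.1°). Polarity flips lag *exogenous* events by a
  per-trial draw from N(129.4, 36.6²) ms, the oculomotor latency after a
  physical stimulus change. For *endogenous* switches the latency is zero
  by construction: during rivalry the percept is **defined** by the OKN, so
  percept and OKN change are the same event and a nonzero offset would be
  unidentifiable.
* **Spikes** are inhomogeneous Poisson. Each unit has a preferred
  direction and a target d′; the nonpreferred rate is fixed at the baseline
  (10 Hz) and the preferred rate is solved in closed form so that 1000 ms
  Poisson counts yield the target d′ (one free parameter per unit). A
  multiplicative transient (`transient_gain` = 2 for 200 ms) applies to all
  units after exogenous switches only, emulating the feedforward burst that
  accompanies a physical stimulus change but not an endogenous rivalry
  switch.
* **Fixation controls** use cosine tuning between the nonpreferred and
  preferred rate across the eight directions. `fixoff_late_gain` (default
  1.25) boosts Fixation-Off rates in the 500–1000 ms window only, emulating
  the late, OKN-linked extra modulation seen when eye movements are free;
  setting it to 1 yields the null case.

The generator does **not** emulate: biophysical OKN dynamics (saccade
kinematics, drift, blinks), correlated noise between units beyond shared
rate modulation, waveform diversity, or electrode drift within a session.
Passing tests therefore demonstrate that the *analysis chain* is correct
and recovers known structure — not that real cortical data behave this way.

## Spike detection

Voltage is band-passed 0.6–3 kHz with a zero-phase second-order Butterworth
filter, and events are detected at −5× the **median** absolute deviation.
The MAD is used raw, without the 0.6745 Gaussian consistency factor — the
convention names the plain statistic — and the factor can be supplied via
`threshold_mad` if a calibrated threshold is wanted. Events whose trough
exceeds 50× the **mean** absolute deviation are discarded as artifacts;
the asymmetry (median for detection, mean for artifacts) is kept literally,
with `artifact_stat = "median"` available since the mean-based reading may
well be a transcription slip in the source convention. Detection is on
negative crossings only (snippets are trough-aligned), the refractory rule
drops the later of any pair closer than 0.5 ms, and snippets take 15
samples before and 29 after the trough (45 total, 1.5 ms): the longer
post-trough tail captures repolarization. Spike sorting is out of scope —
synthetic data carry unit identity.

## OKN segmentation

`segment_percepts()` is an automated surrogate for manual marking (the
original workflow had two humans mark dominance onsets from the slow-phase
change). Velocity is a centred difference over 20 ms; samples above
30 °/s are masked as fast phases; the velocity sign is majority-filtered
over a sliding 200 ms window; maximal constant-sign runs of at least
`min_stable` (300 ms) with mean pursuit speed ≥ 5 °/s become epochs. The
5 °/s floor (about half the slow-phase speed) rejects fixation noise, which
otherwise produces spurious sign runs. On noise-free input boundaries are
exact to within a couple of samples; at the default noise level, switch
times are recovered within ±150 ms in over 90% of trials (this is tested).
PA trials can be analysed either stimulus-aligned (`epochs_from_events()`)
or OKN-aligned (`segment_session()`), mirroring the dual analysis.

The eye-variance trial selection for fixation controls detrends the y
trace (least-squares line), low-passes below 20 Hz (zero-phase 2nd-order
Butterworth — family and order are unstated in the source convention, so
the same filter family as the spike band-pass is used), double-
differentiates, and scores each trial by the summed squared deviation from
a flat line of slope zero whose intercept is fitted by least squares (the
baseline of the double-differentiated signal; an intercept taken from the
position trace instead would dwarf the curvature term and make the score
reflect trace asymmetry rather than smoothness). Trials strictly below the
within-condition median error are
kept — ties therefore select nothing, and with distinct errors exactly
⌊n/2⌋ trials survive.

## Selectivity

The sampling unit for both the rank-sum test and d′ is one 1000 ms
dominance epoch (a BR trial can contribute several; epochs are pooled
across trials — recorded in the output metadata). Switch-aligned analyses
require ≥ 1000 ms of dominance on both sides and an inter-dominance gap
under 250 ms, aligned to the onset of the forward dominance. The rank-sum
test uses the exact distribution when both groups have ≤ 20 untied values
and the tie-corrected normal approximation otherwise (full enumeration
with ties is combinatorially infeasible and the approximation is accurate
at these sizes; the type-I rate is verified at 5% ± 1%). Preference ties
(equal means) yield `NONE` rather than an arbitrary side. d′ uses sample
(n−1) variances (`var_type` switches to population variances).

## Decoding

All decoding uses a maximum-correlation-coefficient classifier: one
template per class (mean training vector), prediction by maximal Pearson
correlation. Correlation ignores per-feature affine rescaling, which is
why counts are z-scored per feature; the statistics are computed on
training folds only and applied to the test fold, avoiding leakage — the
phrasing of the original convention is ambiguous, so `zscore = "global"`
reproduces the literal all-data variant. Ties and zero-variance test
vectors resolve deterministically to the lexicographically first class and
are flagged.

Exemplars are switches, not trials; cross-validation leaves one exemplar
per class per fold (15 splits for switches, 13 for flash suppression, 8
for the reduced-eye-movement control, 7 for the selection-robustness runs)
and is repeated over 50 resample runs; reported accuracy is the zero-one
mean over runs and the dispersion is the SD over runs. For
multi-session pseudopopulations the across-session exemplar pairing is
re-drawn every run; for a single session the true simultaneous pairing is
kept (re-pairing simultaneously recorded trials would destroy real
correlation structure, and the degenerate self-test contract — training
and testing on identical exemplars memorizes perfectly — must hold).
Features constant across all exemplars are dropped at assembly, since a
correlation needs at least two non-constant features.

Cross-temporal matrices use 150 ms bins sampled every 50 ms with shared
fold draws between train and test bins. Cross-condition generalization
trains on all exemplars of one condition in a 400 ms window (−600..−200 or
+200..+600 ms around switches; +400..+800 ms after stimulus onset for the
fixation controls) and tests on the other condition. Cross-session
generalization sums spikes per electrode so the 96 array electrodes give a
feature space that exists in every session; the diagonal is within-session
cross-validation.

The permutation test shuffles labels 500 times with identical parameters
and estimates p = (k+1)/(n+1); when the observed accuracy beats every
shuffle this gives 1/501 ≈ 0.00199, the minimum attainable value.

## Problem sizes and numerical choices

The test suite exercises the full chain at deliberately modest sizes —
about 100 units, 15 exemplars per class, 20–50 resample runs, 500
permutations, 200-trial segmentation checks — chosen so each property is
measured with useful power while the whole suite stays quick to run. The
cross-session experiment uses three sessions with 50% unit turnover
between consecutive ones and weak selectivity (mean d′ 0.3, matching the
rivalry-regime values such recordings typically show), because with strong
selectivity a 96-electrode code saturates and turnover no longer separates
within- from across-session accuracy.

Other fixed choices: PSTH bins are half-open, left-edge labelled;
ensemble normalization divides by the maximum *after* min-subtraction so
traces lie in [0,1] (the literal pre-subtraction maximum is available via
`norm_max = "raw"`); constant traces cannot be normalized and the
transition is skipped with a warning; population PSTHs weight units, not
epochs, equally when epoch counts differ. Gamma fitting is maximum
likelihood on durations rescaled to seconds for optimizer stability, with
parameters reported back on the millisecond scale. All stochastic stages
take explicit seeds and identical configuration yields byte-identical
outputs.

## Known limitations

Segmentation quality degrades gracefully but is untested beyond ~0.3°
positional noise; the generator's instantaneous saccade resets make the
fast-phase masking easier than for real eye traces. The pipeline treats
sessions as exchangeable when assembling pseudopopulations and ignores
slow nonstationarities within a session. Decoding supports exactly two
classes (UP/DOWN), which is what the rivalry design produces; the
classifier itself is k-class but the exemplar machinery is binary.
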