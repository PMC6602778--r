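---
title: "Methods: simulating, detecting and classifying bowel sounds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating, detecting and classifying bowel sounds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibsacoustics)
```

## The problem

Irritable bowel syndrome (IBS) alters gut motility, and motility makes
noise: discrete acoustic events ("bowel sounds") recorded on the abdominal
wall carry information about the underlying contractile activity. This
package implements a complete diagnostic-acoustics workflow around that
idea: four-channel abdominal recordings (one sensor per abdominal quadrant:
RUQ, LUQ, RLQ, LLQ; a two-hour fasted period followed by a 40-minute fed
period) are reduced to discrete bowel-sound events, per-sound acoustic
features are aggregated per participant, and a penalised logistic model
maps the feature vector to an *IBS Acoustic Index* in [0, 1], with values
of 0.5 and above predicting IBS (the boundary is inclusive; there are no
indeterminate results).

Because no public recordings exist for this task, the package treats the
synthetic-data generator as a first-class module: every downstream claim is
validated against simulated cohorts with known ground truth.

## The generative model of a bowel sound

A bowel sound is modelled as a *burst train*: `1-5` bursts, each an
exponentially damped sinusoid

$$s(t) = a\, e^{-d t} \sin(2\pi f t),$$

with carrier $f \sim U(100, 1000)$ Hz (inside the classical bowel-sound
band), damping $d \sim U(20, 200)\ \mathrm{s}^{-1}$ and per-event amplitude
$a$ log-normal around a group-specific scale. Successive burst onsets are
separated by the *component interval time*, drawn log-normally with medians
60 ms (IBS) and 45 ms (healthy), `sdlog = 0.2`.

Why these interval values: the detector must be able to (i) resolve bursts
*within* a sound — which needs intervals above the burst gap (25 ms) and a
damping-interval product $d\cdot\Delta \gtrsim 0.5$ so the envelope valley
between bursts is visible — and (ii) group bursts *into* one sound — which
needs intervals below the event merge gap. Medians of 45-60 ms satisfy both
with margin. The direction and size of the group difference in interval and
burst count are configurable, not asserted facts: only "these families
separate the groups" is part of the stated world.

Event times follow a Poisson process at a group- and period-specific rate:
fasted-state defaults 1.2 (healthy) vs 0.8 (IBS) sounds/s summed over the
four quadrants, multiplied by 1.5 after feeding for both groups (no
group-by-food interaction, matching the repeated-measures analysis below).
Optionally the fasted rate is modulated sinusoidally (period 5400 s, depth
0.5) to emulate migrating-motor-complex cycling; this is off by default and
never used by the tests. Each event is placed at full amplitude on its
origin quadrant's channel and attenuated by the leakage factor (default
0.3) on the other three; Gaussian background noise (RMS 0.01) and labelled
non-bowel artifacts (broadband clicks, 30 Hz rumble; 0.02/s) complete the
scene. All randomness derives from one master seed via a stable
per-participant hash, so any participant can be regenerated independently
and byte-identically.

What the generator does *not* emulate: respiratory and cardiac
interference, body-habitus-dependent attenuation, sensor detachment,
non-stationary noise, or any physiological fluid dynamics. A green
detection test therefore establishes that the detector recovers events of
the assumed damped-sinusoid family at the stated SNR — not field
performance on clinical recordings.

## Detection

Channels are band-passed 60-1500 Hz with a zero-phase FFT-domain mask
(raised-cosine transitions, width 5% of each edge). No filter-design
library is available in the target environment; spectral masking gives
exactly zero phase delay — onsets are not shifted — and meets the
stop/passband contracts (50 Hz rejected to <5% RMS, 300 Hz kept >90%).

The RMS envelope (10 ms frames, 50% overlap) is thresholded at
`median + 4 x 1.4826 MAD(envelope)`. Because the threshold is
noise-floor-relative, detection is invariant to overall gain. Runs above
threshold closer than the merge gap are merged; events shorter than 18 ms
are discarded. The merge gap default is **60 ms**, not the 30 ms one might
first pick: intra-sound component intervals of 40-90 ms leave sub-threshold
gaps of up to ~75 ms inside a single sound, and a 30 ms gap splits such
sounds into several events (measured precision dropped to 0.54). 60 ms sits
just above the 97.5th percentile of those intra-sound gaps; at the module's
reference density of 0.5 events/s this gives precision ~0.996 and recall
~0.91, the residual misses being genuinely overlapping Poisson-coincident
events.

Each detected event is segmented into bursts by envelope peak-picking
(5 ms frames): local maxima at least 15% of the event peak, separated by at
least the burst gap, with an intervening valley below 60% of the smaller
peak. Burst onsets are the 50%-of-peak rising crossings; component
intervals are successive onset gaps. A subtlety worth recording: the first
burst of a sound peaks at the very first envelope sample (the attack is
instantaneous), so the peak-picker explicitly admits boundary maxima —
without this the first burst of every event is silently lost.

Detection runs per channel; events overlapping in time across channels are
one physical sound (leakage places every sound on every channel), and the
copy on the channel with the largest peak envelope is kept — that channel
is the origin quadrant. Exact ties break in the fixed order RUQ, LUQ, RLQ,
LLQ. Detections are scored against truth by greedy one-to-one onset
matching at 50 ms tolerance; precision of an empty prediction set is
defined as 1.

## Features

Per sound: duration, burst number, mean component interval (missing for
single-burst sounds), peak amplitude, RMS energy, zero-crossing rate,
waveform skewness/kurtosis, crest factor; and from the Hann-windowed
magnitude-squared FFT restricted to 60-1500 Hz: spectral centroid,
bandwidth, 85% rolloff, peak frequency, spectral flatness, and 4 subband
energy ratios with edges 60/250/500/1000/1500 Hz (the edges are a package
choice; nothing constrains them). Spectral flatness is computed after
averaging the periodogram in 8-bin blocks: raw periodogram ordinates are
exponentially distributed, which caps white-noise flatness near 0.56;
block-averaging restores the intuitive calibration (white noise ~0.89 in
100-draw Monte-Carlo).

Per participant, the default "final model" registry holds exactly **26
features: 8 time-domain** (burst-number mean/SD, component-interval
mean/SD, duration mean, peak-amplitude mean, quantity density, summed
amplitude) **and 18 frequency-domain** (mean and SD of centroid, bandwidth,
rolloff, peak frequency, flatness and the 4 subband ratios). Counts and
family membership are fixed by design; the identity of each statistic is a
reconstruction, switchable by supplying a different registry. Quantity
density is sounds per second; summed amplitude is the sum of per-sound peak
amplitudes scaled by `reference_duration / duration` so the 120-minute
fasted and 40-minute fed periods are comparable. Aggregation pools both
periods and all quadrants; per-period densities and summed amplitudes are
additionally emitted (`extended = TRUE`) for the group-statistics stage.
Statistics with no usable values (e.g. all sounds single-burst) are missing
and imputed with training-set medians at fit time — never from held-out
data.

## Classifier and evaluation

The classifier is logistic regression fitted by IRLS with an L2 penalty
(default `lambda = 1`) on standardised features, intercept unpenalised,
gradient tolerance 1e-8. The penalty is a package choice: with 68
participants and 26 features an unpenalised fit separates. The IBS Acoustic
Index is the fitted probability; 0.5 and above predicts IBS.

Greedy forward selection maximises LOOCV accuracy and stops after 3
consecutive non-improving additions ("plateau"); when selection is part of
an honest evaluation it is rerun inside each outer training fold
(`loocv(select = TRUE)`). Standardisation and imputation are always refit
per fold; a leakage test asserts that altering a held-out label cannot
change training-fold weights.

Evaluation: LOOCV; a battery of 7 k-fold schemes (k in {2, 5, 10},
stratified and unstratified, plus k = n — the battery's composition is a
documented stand-in, only its size is fixed); and out-of-bag bootstrap with
300 stratified resamples (out-of-bag rather than in-bag is a package
choice). Diagnostic metrics from the 2x2 table (IBS positive): sensitivity,
specificity, PPV, NPV, accuracy with Wilson 95% intervals; likelihood
ratios with log-method intervals (the interval methods are package choices;
only the 95% level is fixed). Division by zero yields infinity with an
undefined interval. The Fisher exact test for subgroup accuracy comparisons
is implemented by exhaustive hypergeometric enumeration and checked against
an independent enumeration.

## Fed/fasted group statistics

Quantity density and summed amplitude are analysed with a random-intercept
linear mixed model, `response ~ group * period + (1 | participant)`, fitted
by maximum likelihood (not REML). The variance ratio
$r = \sigma_b^2/\sigma_e^2$ is profiled out: given $r$, the cluster
covariance inverse has a closed form, so GLS estimates and $\sigma_e^2$
follow analytically and only $r$ is optimised (golden-section on
$\log r$, with the $r = 0$ boundary checked separately). Each coefficient
gets a Wald chi-square on 1 df — an approximation to a Type-II analysis,
adequate here because the design is balanced. The fit matches an
independent ML mixed-model implementation to ~1e-5 in estimates, standard
errors, variances and log-likelihood. Wald tests at these sample sizes are
mildly anticonservative; the type-I error of the interaction test is
verified to sit within binomial error of 0.05 over 500 replicates.

## Numerical and scale choices

* **Test-scale world**: 60 s fasted / 20 s fed per participant at 4 kHz
  (well above twice the band-pass high edge). Full-scale defaults
  (7200 s / 2400 s at 44.1 kHz) are configuration, not code paths: the
  statistical structure is identical and nothing in the implementation
  depends on duration or rate beyond memory.
* Event placement truncates at the recording edge; an event that would
  start within 2 samples of the end is skipped (and omitted from truth).
* Amplitudes are capped at 0.85 before noise so clipping to [-1, 1] is
  rare and truth amplitudes stay physical.
* `segment_bursts` falls back to "one burst" for envelopes too short to
  peak-pick; all-zero segments are an error, flagged upstream.
* Ties: index exactly 0.5 is IBS; origin ties go RUQ first; greedy
  matching breaks distance ties by candidate order.
* LOOCV folds whose training set loses a class are flagged and counted as
  errors (conservative).

## Known limitations

* The detector has no mechanism to split two genuinely overlapping sounds
  on the same channel; at 1.2 sounds/s about 15% of events are
  Poisson-coincident and merge, which compresses (but preserves the order
  of) group density differences.
* The 26-feature registry is a principled reconstruction; real per-feature
  effect sizes are unknowable from the published material.
* The bootstrap pools out-of-bag predictions across replicates; per-metric
  percentile intervals are reported only for accuracy.
* The mixed model covers exactly the balanced two-period random-intercept
  design — no random slopes, no REML, no small-sample df corrections.
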