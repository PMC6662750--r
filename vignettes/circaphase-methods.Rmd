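---
title: "Predicting circadian phase from wearable light and skin temperature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting circadian phase from wearable light and skin temperature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circaphase)
```

## The problem

The timing of the central circadian pacemaker is conventionally read off the
melatonin rhythm: salivary melatonin sampled hourly under constant-routine
conditions, or the urinary metabolite 6-sulphatoxymelatonin (aMT6s) collected
in sequential urine blocks. Both are burdensome; neither supports real-time
monitoring. `circaphase` implements a field-validated alternative: a small
multilayer perceptron (MLP) that maps lagged histories of wrist-worn
blue-light irradiance and skin temperature, averaged into 30-minute bins, to
the instantaneous value of the individual's melatonin (or aMT6s) reference
rhythm. The phase of the predicted rhythm — the clock time of its fitted
peak region — is then an estimate of circadian phase obtainable from
wearable data alone.

## Reference waveforms and measured phase

**Melatonin (constant routine).** Hourly concentrations are resampled to
1-minute epochs by linear interpolation, time is converted to radians
(2&#960; = 24 h), and a *bimodal skewed baseline cosine function* (BSBCF) is
fitted by bounded nonlinear least squares with the 24-h period fixed:

$$f(t) = b + \frac{H}{2(1-c)}\Big[ g(t) - c + |g(t) - c| \Big], \quad
g(t) = \cos\!\big(t - \varphi + v\cos(t-\varphi)\big) + m\cos(2t - 2\varphi - \pi)$$

with baseline $b>0$, peak level $H>0$, width $c \in [-1,1)$, bimodality
$m \in [0,1)$, phase $\varphi \in [0, 2\pi]$ and skewness $v \in [-5,5]$.
At $m=v=c=0$ this collapses to the rectified cosine
$b + H\max(\cos(t-\varphi), 0)$, which the test-suite uses as a closed-form
oracle.

**aMT6s (urine blocks).** The excretion rate of each collection block is
concentration × volume / duration (ng/h), timestamped at the block midpoint,
and a 24-h cosine $f(t) = b + a\cos\big(2\pi (t-\varphi)/1440\big)$ is
fitted with $t$ and $\varphi$ in minutes. Two numerical points deserve
note. First, the source procedure prints the angular factor as $2\pi/24$
while declaring $t$ in minutes and bounding $\varphi$ in $[0,1440)$ minutes;
taken literally that is a 24-minute period, so this package uses
$2\pi/1440$, honouring the stated 24-h period. Second, the printed starting
values name a parameter that does not appear in the formula
("a = 300, c = 500, ∅ = 24"); we read them as $a=300$, $b=500$,
$\varphi=24$ minutes, and back the single start with a phase-grid
multi-start, selecting the lowest residual (ties by start order).

**Center of gravity.** Measured and predicted phase alike are the CoG of one
24-h cycle of the *fitted* curve,
$\mathrm{CoG} = \sum_t t\,(f(t)-b) \big/ \sum_t (f(t)-b)$,
computed over the above-baseline portion of the waveform (weights
$\max(f-b, 0)$). The rectification matters: for a full-period cosine the
signed sum $\sum(f-b)$ is identically zero, so the printed quotient is only
well defined on the above-baseline lobe — which is also how the CoG is
described as an "intensity-weighted mean of the above-baseline portion".
The window starts at the curve minimum (aMT6s) or, for melatonin, at the
first *crossing* from baseline to above $b + 0.02H$ sustained for 10
minutes (the source gives no numeric rule for "first increase above
baseline"; this one is insensitive to the exact percentage because the
BSBCF leaves baseline steeply). Requiring a crossing rather than merely an
above-threshold sample keeps the above-baseline lobe contiguous inside the
24-h window even when it straddles midnight — splitting it would bias the
CoG by hours.

**Extrapolation.** The fitted 24-h profile is tiled backwards over the
ambulatory span (stable phase), or regenerated with period
24 h + the daily acrophase shift between two assessments (drifting phase,
shift-work datasets), then min–max scaled to $[0,1]$; Gaussian noise of SD
0.01 is added from a seeded stream. Noise is optional (`noise_sd = 0`) so
deterministic tests can run noise-free; training uses the noisy target.

**A note on interpolation bias.** Fitting after 1-minute linear
interpolation of *hourly* samples displaces the least-squares optimum: the
interpolant is piecewise linear, not a BSBCF. For the default synthetic
melatonin shape the displacement is ≈15 min in $\varphi$ (and much less in
CoG). `fit_bsbcf(..., resample = FALSE)` fits at the observed timestamps
and recovers generating parameters to well under 1%. The package keeps the
resampling default for fidelity to the reference procedure; the test-suite
exercises both routes and bounds the bias.

## Preprocessing rules

Applied in this order, each marking samples missing rather than deleting
rows, so row counts always reconcile with the missingness mask:

* **Temperature** (2.5-min cadence, °C): logged removal intervals or
  off-wrist epochs → missing; values < 20 °C → missing; values beyond
  3 SD of the remaining series → missing. Left/right sensor pairs are
  averaged into six site variables (sternum passes through); if one side is
  missing at a time point the available side is used, preserving coverage.
  A centred ±12 h moving average (computed over available samples,
  shrinking near the edges rather than discarding 12 h of data at each end)
  is subtracted, the residual z-transformed, and |z| > 2 marked missing.
* **Light** (1-min epochs, device irradiance units): off-wrist → missing;
  wake-time values < 1 unit (clothing-cover artefacts, wake defined by the
  sleep diary, not device scoring) → missing; the remainder floored at 0.01
  and log10-transformed. Thresholds are applied in the stored column's
  unit.
* **Activity** (counts): off-wrist → missing; negatives (interpolation
  artefacts) clamped to 0; z-transform; |z| > 2 → missing. Zero-variance
  series z-transform to zeros rather than NaN (degenerate synthetic
  inputs).
* **Inclusion**: < 50% missing per variable, ≥ 3 days total span, no gap
  > 36 h. Gaps ≥ 3 h within the first day do not exclude the dataset; they
  truncate it to the gap's end (the source lists both an exclusion and a
  truncation rule for these; we follow the truncation).
* **Gap interpolation**: gaps ≤ 1 h — autoregressive fill with order
  min(50, n/4) fitted on the whole series; longer gaps — AR order of half a
  day of samples fitted on the day preceding the gap. Our AR fill forecasts
  forward from the pre-gap history and backward from the post-gap data and
  cross-fades the two linearly; when an AR fit is singular or history is
  insufficient the gap falls back to linear interpolation with a warning,
  never silently.
* **Binning/alignment**: 30-min means, bins starting on the hour/half hour
  with centre timestamps (:15/:45); all channels cut to the shortest
  stream; aligned spans < 1 day rejected.

## The network

Light enters with lags 0–24 h in 30-min steps (49 columns); each
temperature variable with lags 0–5 h (11 columns). One wrist sensor gives
60 inputs and $(60{+}1)\times 5 + (5{+}1) = 311$ weights; six temperature
variables give 115 inputs and 586 weights. Rows lacking the full 24 h of
prior light history are dropped, not zero-padded — padding would fabricate
pre-recording light. Inputs are scaled to the mean/SD of the n−1 training
participants and the identical scaling applied to the held-out participant.

Training is full-batch resilient backpropagation. The original
implementation's activation functions, epoch limits and restart-selection
rule are unpublished, so this package fixes them explicitly: tanh hidden
units and a logistic output (bounding predictions to the $[0,1]$ target
scale); the iRprop− variant with the canonical constants
$\eta^+{=}1.2$, $\eta^-{=}0.5$, $\Delta_0{=}0.07$, $\Delta_{max}{=}50$;
stopping at 1000 epochs or when every per-weight step falls below $10^{-6}$;
100 restarts from uniform(−0.5, 0.5) initialisations on seeded substreams,
keeping the restart with the lowest final training MSE (ties by index).
Restarts with non-finite loss are discarded with a warning.

Validation is leave-one-out by participant. Training targets retain in-lab
rows; *predictions* are emitted only for the held-out participant's
out-of-lab rows, mirroring the rule that only data collected outside the
laboratory are used for validation. A final model trained on all
participants supports application to independent cohorts (e.g., a
diurnal-trained model applied to night-shift recordings).

## Comparators and scoring

Prediction error is measured − predicted clock time, wrapped to
(−720, 720] minutes; summaries include mean, median, SD, absolute-error
statistics, RMSE, percentages within ±15/30/60/120 min, and the
Jammalamadaka–SenGupta circular correlation (the source names only
"circular statistics"; this coefficient with its large-sample normal
p-value is the standard choice). Comparators: the circular-mean mid-sleep
time; a uniform guess over 1.3–7.1 h (the published normal range of aMT6s
acrophase — its analytic mean, 4.2 h, anchors a determinism check); and
resampling from the *other* participants' measured acrophases — the
participant's own value is excluded, otherwise the surrogate trivially
contains the answer.

## The synthetic world

Every pipeline stage is testable without the (request-only) real data via
`gen_cohort()`. Defaults are the observed cohort characteristics: FS sleep
onset 23.30 h, aMT6s acrophase 3.72 ± 1.21 h, bedtime phase angle −4.43 h,
SWnight daytime sleep onset 9.56 h. Ground-truth acrophase is injected
through the target-rhythm generators (BSBCF melatonin profile of 38 hourly
samples; cosine excretion integrated over 4-h blocks, 8 h over sleep), so
reference-fitting error and network error are separable. The phase–light
coupling dial sets how much of each participant's sleep (hence light)
timing is determined by their phase: 1 makes the task identifiable from
light history, 0 reproduces the night-shift regime where the rest–activity
cycle carries no phase information. Wrist temperature carries a circadian
cosine locked to true phase plus a sleep-masking rise and AR(1) noise.

What the generator does *not* emulate: mechanistic light entrainment (no
limit-cycle oscillator — phase does not respond to the light it
generates), weather/seasonal light structure, posture or exercise masking
beyond the sleep rise, assay limits of detection, and realistic day-to-day
phase lability beyond a linear drift. A green end-to-end test therefore
establishes that the pipeline recovers phase when the stated coupling
exists and degrades when it is removed — not that it attains any particular
accuracy on real recordings.

## Numerical choices and degenerate inputs

Bounded nonlinear least squares uses `optim(L-BFGS-B)` with tight
convergence (`factr = 1e2`) and multi-starts (8-point phase grid for the
BSBCF; canonical start plus grid for the cosine); ties break by start
order. Near-flat fits (amplitude < 5% of baseline) are flagged
`degenerate` / `low_amplitude` rather than rejected — the night-shift
large-error cases present exactly so. A waveform that never exceeds
baseline makes the CoG undefined and raises an error. Zero-variance
columns are dropped from designs with a warning; zero-variance z-transforms
return zeros. All randomness (restart initialisation, reference noise,
guessing comparators, cohort generation) derives from one master seed
through named substreams, so identical seeds reproduce identical results
bit-for-bit, including the 100-restart training trajectory.

## Scale of the shipped tests

The acceptance suite runs the identifiability property at n = 16
participants with 3-day recordings (the protocol's minimum inclusion
span), 10 restarts and a 120-epoch cap over 20 cohort replicates, and the
misalignment property on 12 diurnal + 10 night-shift participants — sized
to finish in minutes on one CPU. These reductions shorten recordings and
training, not the assertions: the MAE < 30 min bound and the paired
superiority over the resampling guess are tested as stated.

## Known limitations

The MLP variant differs from the unpublished original in its activation
functions and stopping rule (fixed here by explicit decision); the AR gap
fill approximates a proprietary forward–backward interpolator; drifting
references assume a strictly linear daily shift; and the BSBCF's skewness
makes its $\varphi$ parameter non-identifiable to high precision from
hourly data after linear-interpolation resampling (use the CoG, which is
stable, or `resample = FALSE`).
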