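---
title: "Methods: contactless infant monitoring with cribwatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contactless infant monitoring with cribwatch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cribwatch)
```

## The monitoring problem

Sudden Infant Death Syndrome risk is shaped both by the infant's physiology
(heart rate during sleep) and by the sleep environment (heat stress, CO,
CO2, tobacco smoke, humidity). cribwatch implements a fully non-contact
monitoring pipeline for this setting: heart rate is read from a webcam by
remote photoplethysmography (rPPG), the room is sampled every 120 seconds
by an air-quality sensor node, and each monitoring instant is classified
into a four-level severity scale whose acceptable ranges adapt to context
(season, room occupancy, sleep state, outdoor conditions) and to the
individual infant.

## Heart rate by remote photoplethysmography

Each cardiac cycle changes facial blood volume and therefore the amount of
light the skin reflects. Averaging the pixels of a tracked face region per
frame gives three time series — the red, green and blue channel means —
that are modelled as an instantaneous linear mixture of underlying
sources:

$$\mathbf{x}(t) = A\,\mathbf{s}(t), \qquad \hat{\mathbf{s}}(t) = W\,\mathbf{x}(t),$$

where one source is the cardiovascular pulse and the others are nuisance
terms (motion, illumination). The unmixing matrix $W$ is estimated by
independent component analysis: we maximize the non-Gaussianity of the
projections using the classical negentropy proxy $E[\log\cosh u]$, with a
fixed-point iteration and deflation. The initial directions are drawn from
a seeded RNG, so the whole pipeline is deterministic given its seed.
ICA outputs are defined only up to permutation and sign; everything
downstream is invariant to that gauge.

The pulse frequency is then the location of the highest spectral peak of
the selected component within an operating band of $[0.75, 4]$ Hz,
equivalent to $[45, 240]$ beats per minute — wide enough to span sleeping
adults through newborns. `bpm = 60 f_{peak}`.

```{r}
g <- gen_rgb_trace(trace_scenario(true_bpm = 120, snr_db = 6, seed = 5))
hr_pipeline(g$trace, hr_config(seed = 5))
```

### Design choices the rPPG literature leaves open

* **Preprocessing.** ICA assumes zero-mean, comparable-scale inputs, and
  webcam traces drift with ambient light. Each channel is linearly
  detrended over consecutive windows (`window_s`, default 30 s; the window
  may not exceed the trace) and standardized to zero mean, unit variance.
  A channel that is constant after detrending is zeroed and flagged
  degenerate rather than divided by a near-zero variance.
* **Component selection.** Conventionally the "second" ICA component is
  read as the pulse, but ICA ordering is arbitrary. The default mode
  `max-inband-peak` selects the component with the strongest in-band
  spectral peak, which is invariant to output order; a literal
  `fixed-index` mode (default index 2) is available for fidelity with that
  convention.
* **Spectrum.** Mean-removed, Hann-tapered periodogram, zero-padded to the
  next power of two at least 8 times the window length, so the frequency
  resolution at a 30 Hz frame rate is about 0.002 Hz (~0.1 bpm). The
  estimate is one-sided and Parseval-consistent.
* **Ties and validity.** Equal peak powers resolve toward the lower
  frequency (and lower component index) — conservative and deterministic.
  An estimate is `valid` only when the peak is at least twice the median
  in-band power; a flat spectrum (face lost, camera dropout) must surface
  as *indeterminate*, never as a numeric heart rate of 0, which would
  otherwise masquerade as a cardiac emergency.

## The air-quality stream

The sensor node reports temperature, relative humidity, CO, CO2, smoke
concentration, plus sound and light levels every 120 s — 720 readings per
day. Acceptable ranges default to the indoor maximum-concentration
standard: CO 9 ppm, CO2 900 ppm, tobacco smoke 0.40 ppm, 25 °C, 60 % RH.
Ranges are **closed** intervals: a value exactly at a printed maximum is
still acceptable. The standard gives maxima only; the lower bounds (0 for
gases, 16 °C and 30 % RH comfort floors) are package defaults, marked as
such and configurable, because cold stress matters clinically but is not
part of the printed standard.

Raw streams contain transmission garbage. `validate_readings()` rejects
missing fields, non-finite values, physically impossible values (humidity
outside [0, 100], negative concentrations, temperatures outside
instrument range) and duplicate timestamps per home (first reading kept).
Rejection is a return state and accepted + rejected always equals the
input count.

## Context and personalized thresholds

Fixed limits fire constantly in real homes; what is abnormal depends on
context. `aggregate_context()` discretizes the instant into a key
`season | occupancy | sleep state | outdoor-temperature tercile`:
occupancy requires sound *and* light above their cutoffs, sleep state
comes from the heart-rate estimate (below the configurable `sleep_hr_split`
= asleep; invalid estimate = unknown), and the outdoor temperature is cut
at 10 °C and 20 °C. Finer keys are configuration-extensible; this minimal
key is what the narrative use cases (e.g. a heat wave relaxing the indoor
temperature ceiling) require.

Personalized acceptable ranges are learned per (context key, variable)
once at least `min_n = 30` validated readings exist:

$$[\,\mathrm{median} - k\cdot\mathrm{MAD},\ \mathrm{median} + k\cdot\mathrm{MAD}\,], \qquad k = 3,$$

with the MAD (scaled, consistent-estimator constant 1.4826) floored at a
per-variable resolution so a zero-spread history still yields a usable
band. The rule is robust, needs no RNG, and is auditable. Crucially the
learned range is intersected with hard safety caps: a personalized CO,
CO2 or smoke ceiling can never exceed the statutory maximum, whatever the
history says. Published guidance on threshold personalization for this
design states the goal but not the estimator; median/MAD with statutory
caps is this package's own choice.

For an infant's acceptable heart-rate band no published default exists;
it is a required deployment setting. `load_config()` ships
`heart_rate = c(80, 180)` bpm as a configurable placeholder consistent
with clinical reference ranges for infants, and the sleep split defaults
to 120 bpm — both invented defaults, both configurable.

## Severity classification

Expert rules over the six per-variable out-of-range flags:

| Class | Label | Rule |
|---|---|---|
| 0 | Normal | all values within their expected range |
| 1 | Warning | exactly one value out of range, and not the heart rate |
| 2 | Alert | heart rate out of range, or ≥ 2 air-quality values out |
| 3 | Emergency | all six values out of range |

Two readings of the printed rules are ambiguous and resolved here as:
"all values" in Emergency means all six monitored variables (the strict
reading, maximizing specificity of the top class), and Warning means
*exactly* one air flag, since two or more already escalate to Alert. An
indeterminate heart-rate flag counts as in range for classification but
is recorded, so sustained camera dropout can be routed to a sensor-fault
channel rather than a cardiac alert. The mapping is total and exclusive
(verified by enumerating all 64 flag combinations) and monotone: adding a
flag never lowers the class.

The traditional comparator, `threshold_baseline_classify()`, is binary:
abnormal iff any flag fires. When every personalized range contains the
corresponding standard range, any instant the context model finds
non-Normal is also abnormal under the baseline, so the baseline's
abnormal count dominates the context model's non-Normal count — this is
the provable mechanism behind the context model's false-positive
reduction, and it is tested as an invariant rather than by attempting to
reproduce deployment counts whose raw streams are not public.
`deployment_summary()` ships the published five-home summary table; its
conservation identities (counts summing to per-home totals under both
models) are checked programmatically.

## The synthetic generators

No public recordings exist for this setting, so the package generates its
own inputs with ground truth.

* `gen_rgb_trace()`: pulse source = sinusoid at `true_bpm/60` Hz plus a
  second harmonic at 0.3× amplitude; two nuisance sources (slow baseline
  wander / motion sinusoid / illumination steps, plus white noise); mixed
  by a fixed full-rank matrix (default condition number ≈ 2.9) and
  degraded by per-channel Gaussian noise at a stated SNR. This emulates
  exactly the regime where the instantaneous linear ICA model holds.
  Convolutive mixing, realistic PPG morphology, and face-detector
  behaviour are deliberately out of scope, so passing tests demonstrate
  correct source separation and spectral estimation — not robustness to
  real-video artifacts.
* `gen_frames()`: renders a trace into constant-background frames whose
  ROI pixels carry the channel value plus per-pixel noise, closing the
  loop through `extract_rgb_trace()`.
* `gen_sensor_stream()`: 120-s cadence, per-variable diurnal sinusoid +
  noise around defaults chosen as a plausible temperate-climate bedroom
  (21 °C, 45 % RH, 600 ppm CO2, 0.8 ppm CO, 0.05 ppm smoke), injected
  excursions with per-instant labels, and a seeded corruption model
  (missing-completely-at-random nulls and impossible spikes) to exercise
  validation. Real sensor noise is neither white nor stationary, and real
  occupancy is not a clean diurnal sinusoid; the generator supports
  correctness tests, not sensor calibration claims.

## Problem sizes and numerical notes

The test-suite and the acceptance script use 60-s traces at 30 Hz
(1800 samples), 20 seeded heart-rate scenarios at 6 dB SNR, 10 ICA mixing
seeds, 100 spectral-oracle draws, and 50 one-day sensor streams — sizes at
which every stochastic property is stable across seeds while the whole
suite runs in about a minute. The ICA whitening step refuses inputs whose
smallest singular value is below 1e-8 of the largest (rank-deficient
channels); fixed-point convergence tolerance is 1e-6 on the direction
cosine with a 200-iteration cap; the standardization guard treats a
channel standard deviation below 1e-12 as degenerate.

One caution on synthetic ICA fixtures: periodic sources can be truly
dependent. A 0.3 Hz sawtooth has its 4th harmonic exactly at 1.2 Hz, so
pairing it with a 1.2 Hz sinusoid yields sources with empirical
correlation ≈ 0.19 that no unmixing can separate beyond ≈ 0.975; the
suite's strict (> 0.99) recovery checks therefore use a 0.5 Hz sawtooth
whose harmonics avoid the sinusoid.

## Known limitations

* The rPPG model is instantaneous and linear; convolutive mixing, motion
  beyond additive artifacts, and illumination nonlinearity are out of
  scope.
* Heart-rate accuracy claims are property-based on synthetic traces; no
  published accuracy figure exists for this design to compare against.
* The published five-home deployment counts cannot be reproduced (raw
  streams unreleased); only their internal conservation identities are
  testable.
* Threshold learning assumes contexts recur; a context key seen fewer
  than `min_n` times falls back to the standard set, which is safe but
  not personalized.
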