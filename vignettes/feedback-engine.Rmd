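---
title: "Inside the liftlight feedback engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inside the liftlight feedback engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liftlight)
```

liftlight re-enacts, offline and deterministically, a closed feedback loop
for guided resistance exercise: a single vertical hand-position signal in
mm (up = positive, 30 Hz nominal) drives pitch-transposition sonification,
endpoint earcons, and a breathing light channel. This vignette documents
the models, the tunable parameters, the numerical choices, and what the
synthetic-data generator does and does not emulate.

## The movement model

A repetition is treated as one period of a sinusoid through the calibrated
range of motion: with bottom endpoint $y_{ecc}$, top endpoint $y_{con}$,
midpoint $m$ and amplitude $A = (y_{con}-y_{ecc})/2$,

$$y^*(t) = m - A\cos\!\big(2\pi (t - t_0)/T\big), \qquad T = 6\,\mathrm{s},$$

which encodes the instructed pace of 3 s concentric (lifting) and 3 s
eccentric (lowering). The anchor $t_0$ is the time at which the model sits
at the bottom about to lift. Its velocity $y^{*\prime}(t)$ peaks at
$2\pi A/T$ mid-phase (about 209 mm/s for $A = 200$ mm).

**Phase realignment.** The model's phase is re-anchored at every detected
endpoint rather than continuously: an eccentric endpoint at time $t_e$
sets $t_0 = t_e$, a concentric one $t_0 = t_e - T/2$. Re-anchoring per
endpoint keeps the velocity-error feedback local to the current
half-cycle — a pace correction by the exerciser is reflected in the sound
within the same half-cycle — while avoiding the instability of continuous
phase tracking on a noisy signal. The timing error reported for each
endpoint is the offset to the *nearest* ideal endpoint time of the same
type, so it lives in $(-T/2, T/2]$ and is zero exactly when the completed
half-cycle took $T/2$.

## Smoothing

Raw depth-camera joint positions carry frame-to-frame jitter, so the
engine smooths causally with the double-exponential (Holt) joint-filter
recurrence used by Kinect pipelines, configured as level weight 0.5,
trend-correction weight 0.8, 0.3 frames of forward prediction, and 10 mm
jitter and maximum-deviation radii (the radii arrive as 0.01 in the
capture software's metre convention). Two clamps bracket the recurrence:
deviations of a raw sample from the previous filtered value at or below
the jitter radius are attenuated proportionally toward it, and the final
output is pulled back toward the raw sample whenever it would depart by
more than the max-deviation radius. The filter is strictly causal; the
warm-up uses the two-sample mean at the second sample.

Two consequences matter downstream:

* the filter has a group delay of roughly 3 frames (~0.1 s) at the default
  settings, so turning points detected on the smoothed signal lag the true
  reversal; and
* with a 10 mm jitter radius and typical inter-frame steps below 7 mm,
  the jitter attenuation is always active, which is intended — it is what
  suppresses sensor jitter — but adds to the delay.

Because of the delay, detected endpoints are *re-localised on the raw
signal*: each endpoint's reported time and position are the raw extremum
within ±0.25 s of the smoothed detection. Detection robustness comes from
the smoothed signal; reported coordinates come from the measurement. The
0.25 s window covers the filter delay with margin while staying below half
of the minimum half-period, so re-localisation cannot reorder endpoints
(an ordering violation, possible only in pathological inputs, reverts that
endpoint to its smoothed coordinates).

## Endpoint detection and repetition parsing

Turning points are found with an online zigzag scan: a candidate extremum
is confirmed as an endpoint when the signal reverses away from it by at
least `min_prominence_mm` (default 20 mm, roughly 5–10 % of a typical
arm-exercise range) and the candidate lies at least `min_half_period_s`
(default 0.5 s) after the previously confirmed endpoint. Reversals that
arrive too soon are absorbed into the current candidate, so emitted
endpoints always alternate between maxima (concentric) and minima
(eccentric). Ties between equal samples resolve to the earliest sample.
Only interior extrema — confirmed on both sides — are emitted.

Sets are assumed to start and end at the lowered position, so the
analysis pipeline anchors the sequence with the first and last trace
samples as eccentric endpoints when the detected sequence starts or ends
concentric. A repetition is an (eccentric, concentric, eccentric) triple;
the trailing eccentric endpoint starts the next repetition, and a
trailing unpaired endpoint is dropped. Contraction times are timestamp
deltas, never sample counts, so irregular frame intervals are handled.

Per-set metrics use the sample SD ($n-1$ denominator) throughout — the
convention for within-set variation; an empty set yields zero metrics
rather than `NA` so that summaries never propagate missing values.

## Sonification

The velocity error $v(t) - y^{*\prime}(t)$ (measured minus ideal) is
mapped linearly onto a transpose dial clamped at ±1 octave:

$$\tau(t) = \mathrm{clamp}\big((v - v^*)/\Delta v_{sat},\,-1,\,+1\big).$$

* `base_low_hz` = 185, `base_high_hz` = 247: the melody band. With the
  octave clamp the emitted range is 92.5–494 Hz.
* `dv_sat_mm_per_s` defaults to the reference peak velocity $2\pi A/T$:
  a complete stop, or a doubled pace, at mid-phase just reaches the clamp,
  which makes the dial's full range musically meaningful.
* Polarity is configurable; the default raises pitch when moving faster
  than the reference.
* Transposition is continuous (a "dial"), not semitone-quantised.

Measured velocity uses central finite differences (one-sided at the two
boundary samples), which carries one frame of lookahead; the engine's
causality contract is therefore exact up to a single 33 ms frame. On an
ideally paced set processed without smoothing the transpose dial stays
below 0.01 octave at interior samples (the boundary samples carry the
one-sided estimate's $O(h)$ error, analytically below 0.03 octave at the
default saturation). With the default smoothing filter the residual
transposition reflects the filter's lag rather than a pace error; it
stays well inside the clamp (mean < 0.1 octave on a perfect set) and is
the honest price of causal smoothing.

Reached endpoints are classified against the calibration with a symmetric
band (`tolerance_mm`, default 20 mm): `success` within the band,
`overshoot` past the target by more than the band in the movement
direction (above the top target, below the bottom target), `undershoot`
otherwise. Success and overshoot produce earcons (concentric variants
nominally 660/622 Hz, eccentric 440/415 Hz — payload metadata only, no
audio is mandated); undershoot produces silence. The set-start anchor is
the resting position, not a reached endpoint, and draws no earcon. A
repetition completes at each eccentric endpoint; the set-complete earcon
fires once, when the counter reaches the configured set size (default
10).

## Breathing channel

The light pacer is a triangular wave: minimum to maximum brightness over
3 s and back over 3 s, one breath per 6-s repetition. Exhalations are
detected from a normalised RMS envelope (0.1 s causal windows, hop = half
window, full windows only so a trailing fragment cannot distort the
normalisation; global-max normalisation with a $10^{-6}$ silence guard
makes detection invariant to recording gain). Hysteresis thresholds open
an event at 0.2 and close it below 0.1; events closer than 0.5 s merge,
events shorter than 0.3 s are discarded. The defaults suit breath
recordings where exhalations are the dominant bursts — the microphone
sits at the mouth and records little else.

The breath-hold (Valsalva) monitor emits `lights_off` exactly 6 s after
the *end* of the last exhalation ("no respiration for 6 s" reads most
naturally as 6 s of silence; onset-referencing is available), or 6 s
after the set start if no exhalation ever occurs. The next exhalation
onset emits `lights_on` and restarts the pacer from minimum brightness,
re-cueing a fresh inhale — the original system does not document
resumption, so this is the package's design choice. The three physical
lamps of the original setup are modelled as one logical channel since
they were driven identically.

## The synthetic generator

`gen_motion()` concatenates half-cycle cosine segments: smooth velocity,
zero at the endpoints, matching the sinusoid-like character of real
repetitions and making analytic checks possible. Per-half-cycle durations
are $N(\mu, \sigma^2)$ truncated at 0.5 s (shorter half-cycles are not
physiologically plausible and would be undetectable at 30 Hz); endpoint
targets are midpoint ± amplitude plus a systematic bias and per-endpoint
jitter; white noise is added per sample. Defaults describe the instructed
ideal — 3 s / 3 s, 10 repetitions, 400 mm range (100–500 mm, a typical
bicep-curl hand excursion relative to the centre of mass) — and a
"control-like" pace is obtained by setting the concentric mean to 2.17 s,
the unassisted pace observed in practice. `gen_breath()` places Hann
bursts (amplitude 0.8 over a 0.05 noise floor, 1 s long) at each
concentric endpoint in paced mode, walks with jittered ~4 s gaps in free
mode, and silences hold intervals completely in holding mode.
`gen_session()` derives per-set sub-seeds from the master seed by a
multiplicative-congruential hash of the (exercise, set) indices, keeping
every set individually reproducible. All generators restore the caller's
RNG state.

What the generator does **not** emulate: between-participant variance
(its knobs are within-set only, so summary SDs of simulated cohorts are
not comparable to mixed human cohorts), fatigue drift across sets,
asymmetric or skewed pace distributions, sensor dropouts, and any
coupling of breathing effort to movement load. Tests passing on this
generator therefore demonstrate the engine's correctness and calibration
recovery, not fidelity of any human-study statistics.

## Numerical and degenerate-input conventions

* Durations always come from timestamps; sample rate is nominal metadata.
* Endpoint ties resolve to the earliest sample; classification bands are
  closed (a position exactly at tolerance is a success).
* The exhalation count uses a half-open window $[t_{start}, t_{end})$.
* Empty inputs: smoothing requires ≥ 2 samples, velocity ≥ 3; an empty
  endpoint stream yields zero repetitions and zero metrics; an empty run
  collection refuses to summarise.
* The pitch map refuses an unset saturation bound rather than guessing.
* Invalid inputs raise a typed condition (`liftlight_invalid_input`).

## Problem sizes

The package's statistical self-checks run at sizes chosen to make
sampling error negligible next to the tested tolerances: 10-repetition
sets at 30 Hz (1801 samples), Monte-Carlo pace recovery over 200 sets
(2000 repetitions, 3-standard-error bands plus one quantisation frame),
and a 100-set round-trip of the control-like 2.17 s profile.

## Known limitations

* The smoothing recurrence follows the published Kinect joint-filter
  semantics; the original capture plug-in's internal prediction details
  are not public, so agreement is by convention, not bit-exactness.
* Endpoint variation is reported in mm; no attempt is made to reconcile
  sources that print the same numerals in cm.
* The engine is single-channel (one y-coordinate); exercises that need a
  different limb or axis must be reduced to one vertical series upstream.
* "Real time" is modelled as causal streaming over recorded inputs; no
  audio is rendered and no lamp protocol is spoken.
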