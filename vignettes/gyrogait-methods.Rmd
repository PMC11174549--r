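---
title: "Shank-gyroscope gait detection: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shank-gyroscope gait detection: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gyrogait)
```

## The model

A gyroscope strapped to the shank measures the segment's angular velocity
about the pitch (sagittal-plane) axis, `ω(t)` in rad/s, nominally at 200 Hz.
Each gait cycle produces a stereotyped signature: a trough at toe-off (TO)
as the shank rotates backward to unload the foot, a large opposite-sign peak
at mid-swing (MSW), and a second trough at initial contact (IC). Step
counting reduces to detecting the TO → MSW → IC triplet; step length comes
from the net angular excursion of the shank between TO and IC.

The angular displacement is accumulated by rectangular (left-point)
integration of `ω·Δt` with the *actual* inter-sample intervals, split into a
positive bucket `θ⁺` and a negative bucket `θ⁻`. The step angle is the
dominant bucket, sign preserved:

$$\theta = \begin{cases}\theta^{+} & \theta^{+} \ge |\theta^{-}|\\
\theta^{-} & \text{otherwise,}\end{cases}$$

which is what lets the same machinery recognise backward steps (dominant
negative excursion). Distance is the chord of a circle of radius `L` (the
athlete's configured leg length) subtending `θ`:

$$d = L\sqrt{2(1-\cos\theta)} = 2L\sin(|\theta|/2), \qquad 0 \le d \le 2L.$$

We compute the `2L sin(θ/2)` form: it is algebraically identical, even in
`θ`, and numerically stable near zero. `|θ| > π` is clamped to `π` with a
warning — beyond `π` the chord is non-monotone and no single step sweeps
further. The source rendering of this formula is typographically garbled;
the chord reading is the only one consistent with the accompanying geometry
(and with `d(θ=π/3) = L`).

Assumptions worth stating: the leg behaves as a rigid pendulum of effective
length `L` within one step (no double-float correction); the pitch axis of
the sensor is aligned with the anatomical flexion–extension axis; and
left/right sensor assignment is handled by the `event_polarity` convention
below.

## Parameters

| Parameter | Default | Units | Meaning / why this value |
|---|---|---|---|
| `magnitude_threshold` | 1.0 | rad/s | Minimum TO/IC extremum magnitude; rejects sub-gait oscillation |
| `refractory` | 0.250 | s | Minimum IC-to-IC separation between detected steps |
| `flight_time_min` | 0.080 | s | Shortest plausible TO→IC interval; rejects noise doublets |
| `flight_time_max` | 1.500 | s | Times out stalled detections; the machine aborts to SEEK_TO |
| `hysteresis` | 0.1 | rad/s | Retreat needed to confirm a causal extremum decision |
| `event_polarity` | `to_ic_negative` | — | Sign convention: TO/IC troughs negative, MSW positive |
| `filter_order`, `filter_cutoff` | 2, 5.0 | —, Hz | Butterworth low-pass of the published pipeline |
| `leg_length` | per athlete | m | Chord radius `L`; must lie in (0.2, 1.5) |

The flight-time bounds and the hysteresis are engineering guards: the
published workflow demands "flight-time consistency" without stating bounds,
and a real-time extremum decision needs a retreat margin; both are exposed
in `detector_config()`.

### Refractory semantics

The published description says the algorithm "waits 250 ms before
restarting" the TO search after a step, justified by a maximum plausible
step rate (whose printed arithmetic — 8 steps/s versus 250 ms — is
internally inconsistent; we use the printed 250 ms). A literal hard block of
the TO *search* caps the detection rate at `1/(0.25 + flight)` ≈ 3 steps/s,
which contradicts the stated separability requirement
`cadence × refractory < 1` for the faster paces (sprinting at 3.8 steps/s
has a 263 ms period). We therefore implement the refractory as an *emission
ban*: candidate tracking for the next TO continues immediately, but no step
may complete within 250 ms of the previous initial contact. This preserves
exactly the stated invariant ("no two emitted steps have IC times closer
than the refractory") and the double-count protection (two IC troughs
100 ms apart still yield one step), while keeping 3.8 steps/s detectable.

### Causal extremum confirmation

A candidate extremum is the running best polarity-adjusted sample of the
current phase; it is confirmed when the signal retreats from it by the
hysteresis. Two refinements proved necessary in practice:

* **Fresh-excursion seeding (TO).** After a step completes, the decaying
  tail of the IC extremum is often still above threshold; without a guard it
  would immediately seed the next TO candidate and misframe subsequent
  events. TO candidates are therefore only seeded while the
  polarity-adjusted signal is *rising* — the tail of a completed event
  monotonically decays and can never qualify, while every genuine new trough
  is approached on a rising magnitude.
* **MSW resolution floor.** MSW carries no magnitude threshold, but a
  candidate smaller than the hysteresis cannot be distinguished from filter
  ripple by the retreat rule (the 2nd-order low-pass under/overshoots by a
  few hundredths of rad/s around sharp events). MSW candidates must
  therefore exceed the hysteresis (0.1 rad/s) — a resolution limit of the
  causal decision rule, not a gait threshold.

### Backward steps and polarity adaptation

After each emitted step the expected displacement sign under the current
event polarity is `-e` (the displacement is dominated by the opposite-sign
mid-swing lobe). A step whose `θ` contradicts it flips the search polarity;
a subsequent agreeing step flips it back. One consequence is intrinsic and
worth knowing: entering a backward bout under forward polarity frames the
transitional step from one mid-swing to the next, merging the first two true
steps — exactly one step is lost per polarity transition, and the same
happens on returning to forward gait. This is a property of the published
adaptive scheme itself (backward walking is reported as the weakest pace for
this device class); analyses of pure backward trials should set
`event_polarity = "to_ic_positive"` instead of relying on adaptation.

## Preprocessing

Filtering is a causal single-pass 2nd-order Butterworth (bilinear transform
with prewarping), because the pipeline claims real-time operation; a
zero-phase forward–backward option exists for offline work. The filter state
is initialised at steady state for the first sample, so a held constant
passes through exactly and stream starts produce no transient. The ~35 ms
group delay at gait frequencies shifts event *times* but cancels in
IC-to-IC spacing and barely affects displacement windows. Filtering assumes
the nominal rate and warns when timestamp jitter exceeds 20%; integration
always uses actual `Δt`.

Multi-device alignment uses the three vertical jumps recorded at session
start: both rectified streams are low-passed, checked for the presence of
three spike clusters (99th-percentile threshold within the search window —
any monotone detector consistent with the cross-correlation contract would
do), and cross-correlated over ±5 s with parabolic sub-sample refinement.

## The synthetic generator: what it does and does not emulate

Real validation data for this device class are not shareable, so the
generator produces the *stated world* the tests run in: per-pace shank
waveforms on the published six-segment, 201.6 m circuit, with three sync
jumps, quiet rest gaps, additive white measurement noise, backward polarity
inversion, per-step irregularity for run-CoD (angle jitter) and dribbling
(amplitude jitter), and two-device variants with gain mismatch, extra noise
and clock offset. Each cycle is three raised-cosine lobes
(trough–MSW–trough, optionally separated by short gaps) followed by quiet
stance; the MSW lobe area *is* the target step angle
(`width = 2·θ/amplitude`), so the displacement-selection rule applied to the
noise-free waveform recovers `θ` to rectangular-integration accuracy
(<0.5% at 200 Hz), and ground-truth distances are exact chords. Cadences and
step angles (walking 1.8 steps/s at 0.55 rad … sprinting 3.8 steps/s at
0.85 rad) are the stated simulator world; amplitudes and lobe widths were
chosen once, at design time, to be detectable after 5 Hz filtering and to
match field magnitudes (mid-swing peaks ~4 rad/s walking to ~15 rad/s
sprinting), and are not tuned thereafter.

What a green closure test establishes: on noise-free sessions, detected
count equals ground truth exactly at every default pace (with polarity
matched to the direction of travel), per-step *unfiltered* angle recovery is
within 1%, and per-step *filtered* distance error is below 2% at every pace
except sprinting. What it does not establish: performance on real signals —
the generator has no soft-tissue artifact, no sensor saturation, no
mis-alignment of the pitch axis, no true biomechanical variability, and its
noise is white.

The sprinting exception is physics, not tuning: at a 3.8 steps/s fundamental
a 5 Hz 2nd-order filter sheds ~12% of the waveform's energy, and the TO/IC
troughs — which must stay above the 1 rad/s threshold after filtering, hence
cannot shrink below a minimum area — smear into the mid-swing lobe and
cancel part of its positive area. Across realistic waveform geometries the
filtered per-step distance error floor at this cadence is ~6–12% (an
*underestimate*, matching the underestimation the original device reports
for sprinting); the generator's sprint profile sits near that floor (~8%,
documented envelope 10%). All slower paces close below 2%.

## Statistics

* **CCC** uses population (1/n) moments with Lin's z-transform CI.
* **Repeated-measures LoA** fits `d_it = μ + a_i + e_it` by REML (lme4) and
  reports `μ ± 1.96·√(σ̂²_a + σ̂²_e)`; with one subject or single replicates
  it falls back to classical Bland–Altman with a warning, to which it also
  reduces exactly when every subject has one replicate. CIs are
  subject-level (cluster) bootstrap percentiles — subjects are the
  independent units of the design.
* **TDI** solves the normal-model containment equation numerically
  (`Φ((κ−μ)/σ) − Φ((−κ−μ)/σ) = p`); a Monte-Carlo containment oracle guards
  the choice in the tests. Note `TDI(μ=1, σ=1, p=.95) = 2.646`.
* **CIA** compares the mean within-device mean-squared deviation (average of
  the two devices' replicate MSDs, i.e. twice the sample variance) to the
  between-device MSD of all replicate pairs, cell means pooled across
  subject×activity cells before taking the ratio; per-lap repeats within a
  subject-activity cell are the replicates. Values above 1 warn and are not
  clipped.
* **Variance components** are fitted with `lme4::lmer` (the tool the
  original analysis used): fixed device effect plus random subject,
  activity, subject×activity and subject×device terms (`"final"`), with
  `"full"` adding device×activity and `"additive"` dropping interactions;
  `compare_models()` ranks variants by ML-based AIC (then BIC) so criteria
  are comparable across random-effects structures, while components are
  reported from REML fits.
* **MAPE** is the mean of per-observation absolute percentage errors, the
  standard definition.
* **Inter-unit CV** is ambiguous in the source literature; the default is
  `SD(within-pair differences) / grand mean of paired values`, with a
  classical within-pair RMS alternative (`cv = "rms_pairwise"`). No claim is
  made to reproduce any published CV value.

## Numerical choices and degenerate inputs

Half-open `[start, end)` windows assign samples and steps to segments (no
double counting); ties in displacement selection go to the forward bucket;
non-finite samples are skipped and counted, non-monotone timestamps are an
error; an all-zero stream yields zero steps; config JSON rejects unknown
keys outright. All randomness (generator jitter and noise, bootstraps) is
seed-controlled and bitwise reproducible.

## Known limitations

* One step is lost at every direction transition under adaptive polarity
  (see above).
* Filtered sprint distances are systematically ~6–10% short of the chord of
  the true angle; slower paces are within 2%.
* The chord model ignores pelvis translation during double support, so
  absolute distances depend on the calibration of `L` (whether users
  interpret it as full leg or shank-plus-adjustment is a calibration choice,
  not something the algorithm can disambiguate).
* `loa_repeated` assumes a constant bias across replicates within subject;
  heteroscedastic biases widen the bootstrap CIs but are not modelled.
* The TDI is a normal-model estimate; heavy-tailed difference distributions
  will under-cover.
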