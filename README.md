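# gyrogait

Step detection and per-step distance estimation from a **shank-mounted
gyroscope**, plus the full agreement-statistics suite used to validate such
devices — aimed at sports scientists and wearable-device engineers who need
indoor-capable (GNSS-free) load monitoring for soccer-style movement:
walking, jogging, sprinting, running with changes of direction, ball
dribbling and backward locomotion.

## The method

During gait, the shank's angular velocity about the sagittal-plane pitch
axis, `ω(t)` (rad/s), shows a stereotyped pattern per step: a trough at
**toe-off (TO)**, an opposite-sign peak at **mid-swing (MSW)**, and a second
trough at **initial contact (IC)**. The detector is a causal, real-time
state machine over the 5 Hz low-passed signal (2nd-order Butterworth):

1. **SEEK_TO** — find an event-polarity extremum with `|ω| ≥ 1 rad/s`;
2. **SEEK_MSW** — find the subsequent opposite-sign extremum (no magnitude
   threshold);
3. **SEEK_IC** — find the next event-polarity extremum with `|ω| ≥ 1 rad/s`,
   subject to a flight-time window `80 ms ≤ t_IC − t_TO ≤ 1500 ms`;
4. emit the step, reset the integrators, and refuse to complete another step
   within the 250 ms refractory interval (no two ICs closer than 250 ms).

Candidate extrema are confirmed causally when the signal retreats by a
0.1 rad/s hysteresis. From TO onward, `ω·Δt` increments accumulate into
separate positive (`θ⁺`) and negative (`θ⁻`) buckets; the step angle is the
dominant one, sign preserved — a dominant negative displacement is a
**backward step**, after which the search polarity inverts until a forward
step is seen again. Per-step distance is the chord of a circle of radius `L`
(leg length) subtending `θ`:

    d = L·√(2·(1 − cos θ)) = 2·L·sin(|θ|/2),   0 ≤ d ≤ 2L

Integrators reset after every step, so gyro bias contributes at most
`bias × flight time` per step and never accumulates.

Because the original validation data (15 athletes on a 201.6 m six-pace
circuit, 13,202 video-tagged steps) are not publicly shareable, the package
ships a **synthetic-session generator** with exact ground truth, and the
**validation statistics**: MAE/RMSE/MAPE, Lin's concordance correlation
coefficient (CCC), repeated-measures Bland–Altman limits of agreement via a
mixed model on paired differences, the total deviation index (TDI), the
coefficient of individual agreement (CIA), variance-component models
(via `lme4`), and inter-unit reliability summaries.

## Worked example

```r
library(gyrogait)
athlete <- athlete_config("demo", leg_length = 0.9)
session <- generate_session(athlete = athlete, laps = 1, seed = 42)
filtered <- lowpass(session$series)
result <- detect_steps(filtered, detector_config(), athlete,
                       segments = session$segments)
print(result)
```

```
<session_result> 371 steps, 197.4 m total
  per segment:
 lap           pace reference_m n_steps_truth   start    end n_steps distance_m
   1        jogging        25.0            43   5.910  24.05      43   24.48052
   1        run_CoD        42.3            69  24.955  49.56      69   43.48194
   1       backward        16.0            36  50.465  74.57      35   15.58825
   1 ball_dribbling        42.3           105  75.475 109.89     104   41.80065
   1        walking        26.0            53 110.795 141.84      53   25.90570
   1      sprinting        50.0            67 142.745 161.98      67   46.19128
```

371 of 373 ground-truth steps are recovered: one step merges at each of the
two direction flips around the backward segment (entering backward gait with
forward polarity frames the transitional step mid-swing-to-mid-swing — an
intrinsic property of the adaptive state machine, and the reason backward
walking is the hardest pace for this device class). Per-segment distances
track the tape-measured references; sprinting is slightly underestimated
because a 5 Hz 2nd-order filter necessarily sheds energy at a 3.8 steps/s
fundamental:

```r
em <- error_metrics(result$per_segment$distance_m,
                    result$per_segment$reference_m)
cat(sprintf("distance MAE %.2f m, RMSE %.2f m, MAPE %.1f%%\n",
            em$mae, em$rmse, em$mape))
#> distance MAE 1.09 m, RMSE 1.66 m, MAPE 2.8%
```

First detected steps (`theta` in rad, `distance` in m):

```
   t_to t_msw  t_ic     theta  distance direction
1 6.065 6.220 6.360 0.6405563 0.5666950   forward
2 6.445 6.605 6.745 0.6425522 0.5683997   forward
3 6.830 6.990 7.130 0.6423648 0.5682397   forward
```

## Command line

```sh
Rscript inst/exec/gyrogait simulate --laps 5 --seed 42 --out session/
Rscript inst/exec/gyrogait detect --input session/gyro_device1.csv \
    --leg-length 0.9 --out steps.csv
Rscript inst/exec/gyrogait agree --estimated est.csv --reference ref.csv \
    --out report.json
```

(after installation the launcher also lives at
`system.file("exec", "gyrogait", package = "gyrogait")`).

## Documentation

See the methods vignette (`vignettes/gyrogait-methods.Rmd`) for the model,
every threshold with units and defaults, what the synthetic generator does
and does not emulate, numerical choices, and known limitations.
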