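# neuromech

Linking motor unit discharge, muscle fascicle kinematics and joint torque
during isometric contractions.

## What this package is for

When high-density surface EMG is decomposed into motor unit spike trains
while the same muscle region is imaged with B-mode ultrasound and joint
torque is recorded, the chain from neural drive to mechanical output
becomes observable: fluctuations in the **cumulative spike train** (CST,
the per-sample sum of all units' discharges) precede fluctuations in
**fascicle shortening**, which precede fluctuations in **torque**.
`neuromech` implements the full analysis for such experiments:

* spike-train cleaning, CST construction, discharge-rate statistics and a
  silhouette (SIL) decomposition-quality gate (0.86 by default);
* zero-phase band conditioning (4th-order Butterworth, 2 Hz lowpass then
  0.75 Hz highpass, forward–backward) and windowed cross-correlation in
  5-s segments with 50 % overlap: per-window peak coefficient `r` and lag
  (positive = first signal leads) for CST–fascicle, CST–torque and
  fascicle–torque;
* pyramidal Lucas–Kanade **affine optical flow** fascicle tracking from
  image sequences, pennation angles, and cubic-spline resampling onto the
  2048-Hz signal clock via the 80-Hz frame trigger;
* motor unit **recruitment / de-recruitment thresholds** read in two
  coordinate systems — %MVC torque and Δ fascicle length (shortening from
  rest) — after trapezoid segmentation (ramp-up / plateau / ramp-down);
* spike-triggered 2-D MUAP templates and cross-correlation matching
  (>0.80) for tracking the same unit across conditions;
* group-level paired contrasts with 95 % CIs and marginal effects over a
  (muscle length × torque × contraction mode) condition grid;
* a deterministic **synthetic-experiment generator** (motoneuron pool with
  exponential recruitment ladder, common-drive fluctuations, pure-shift
  delayed mechanics, multichannel EMG, speckle ultrasound frames, frame
  trigger) whose injected latencies — drive→fascicle ≈ 75 ms and
  drive→torque ≈ 150 ms — are exact ground truth for every estimator.

The central delay model, in the notation used throughout: with drive
`s(t)`, fascicle length `L(t) = L0 − A·s(t − Δf)` and torque
`T(t) = B·s(t − Δf − Δt)`, the band-limited windowed cross-correlation
must recover lags `Δf`, `Δf + Δt` and `Δt` for the three pairings.

See the methods vignette (`vignettes/neuromech-methods.Rmd`) for the model
assumptions, parameter defaults with units, and known limitations.

## A worked example

Simulate one 20 %MVC ramp-hold trial, segment it, and estimate the
electromechanical delays and thresholds:

```r
library(neuromech)

trial <- simulateTrial(protocolConfig(target_level = 20), seed = 42,
                       emg = FALSE)
trial
#> TrialRecording: 77824 samples @ 2048 Hz; 3040 frames @ 80 Hz; 7 units;
#>   delays 75/75 ms; seed 42

seg <- segmentContraction(trial@torque_pct, 20, 2048)   # ~29.8 s plateau
tm  <- alignTrigger(trial@trigger, 2048, 80)
rs  <- resampleToEmg(trial@truth_fascicle, tm)
pl  <- seg@plateau[1]:seg@plateau[2]
cst <- cumulativeSpikeTrain(cleanDischarges(trial@spikes))

dm <- delayMatrix(
  conditionSignal(as.numeric(cstCounts(cst))[pl], 2048, label = "CST"),
  conditionSignal(trial@torque_pct[pl], 2048, label = "torque"),
  conditionSignal(rs$delta_mm[pl], 2048, label = "fascicle"),
  lag_max_ms = 350)
for (s in dm) show(s)
#> XcorrSummary [CST-fascicle]: mean r = 0.680, mean lag = 62.0 ms (10 windows)
#> XcorrSummary [CST-torque]: mean r = 0.683, mean lag = 137.9 ms (10 windows)
#> XcorrSummary [fascicle-torque]: mean r = 0.969, mean lag = 81.9 ms (10 windows)
```

The CST leads fascicle shortening by roughly the injected 75 ms and
torque by roughly 150 ms; fascicle leads torque by the remaining ~75 ms.
Coefficients near 0.7 for the CST pairings reflect the calibrated
common-drive signal-to-renewal-noise ratio; fascicle–torque is higher
because both are mechanical descendants of the same drive. On a single
trial the lag means carry ±10–20 ms of Monte-Carlo scatter (11 windows);
cohort means converge to the injected values.

Thresholds in both coordinate systems, one row per unit:

```r
th <- thresholdRecords(trial@spikes, trial@torque_pct, rs$delta_mm, seg)
round(th[, c("rt_pct", "drt_pct", "rt_delta_mm", "drt_delta_mm")], 2)
#>   rt_pct drt_pct rt_delta_mm drt_delta_mm
#> 1   0.01    2.28        0.04         0.72
#> ...
#> 7  13.05   17.25        5.22         6.30
```

Because torque lags the drive, the torque read at a unit's last discharge
exceeds that at its first — the model's causal-transmission signature
(the vignette discusses why in-vivo data show the opposite torque-coordinate
ordering, and which hysteresis mechanisms that requires).

Group-level worked example against the bundled published group means:

```r
arch <- referenceGroupMeans("architecture")
rest <- arch[arch$condition == "rest", ]
marginalEffect(rest, "fascicle_length_mm", "length",
               levels = c("short", "long"))
#> Paired contrast: mean diff -14.3, 95% CI [NA, NA], p = NA, n = 1
```

A whole simulated cohort over the 2×2×2 condition grid:

```r
report <- runPipeline(pipelineConfig(n_subjects = 10, seed = 1))
writePipelineReport(report, "cohort_report")
```

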