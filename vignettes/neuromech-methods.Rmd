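---
title: "From motor unit discharge to fascicle shortening and torque: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From motor unit discharge to fascicle shortening and torque: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(neuromech)
```

## The problem

During a voluntary isometric contraction, the chain from neural command to
measurable joint torque has at least two mechanical way-stations: the
discharges of the recruited motor units drive fascicle shortening, and the
shortening stretches the series-elastic tissue that finally transmits
torque to the dynamometer. Concurrent high-density surface EMG (decomposed
into motor unit spike trains), B-mode ultrasound of the same muscle region,
and torque recording make each link observable. This package implements the
analysis chain for such experiments — and, because raw human datasets of
this kind are rarely shared, a synthetic-experiment generator that
reproduces their statistical structure with known ground truth, so every
stage of the analysis can be verified quantitatively.

The canonical experiment the defaults describe is isometric ankle
dorsiflexion with the tibialis anterior imaged through an
ultrasound-transparent 32-electrode grid: ramp-hold contractions (ramps of
10 %MVC/s, 30-s holds at 20 or 40 %MVC) and sinusoidal torque tracking
(0.5 Hz, ±2.5 %MVC), at two ankle angles giving a short (rest fascicle
length ≈ 60.2 mm) and a long (≈ 74.5 mm) muscle length, with signals at
2048 Hz and imaging at 80 frames/s synchronized by an 80-Hz trigger pulse.

## Analysis chain

**Cumulative spike train (CST).** Decomposed discharge trains are cleaned
deterministically — discharges closer than 20 ms are collapsed to the first
(duplicate assignments), inter-spike intervals above 250 ms are flagged as
likely missing pulses but never imputed, since re-estimating pulses
requires the decomposition internals — and summed per sample into the CST,
the standard proxy for net neural drive. Decomposition quality is scored by
a silhouette-type measure (`computeSil`): squared source-peak amplitudes at
the claimed discharges against the remaining local maxima, two-means
clustered; units pass at a 0.86 gate by default (a deliberately
conservative setting for low-electrode-count montages; 0.9 is the common
gate in easier recordings).

**Conditioning.** CST, torque and fascicle shortening are restricted to a
common fluctuation band, 0.75–2 Hz, by a 4th-order Butterworth lowpass at
2 Hz followed by a 4th-order highpass at 0.75 Hz, each applied
forward–backward. We read "4th-order zero-phase" as a 4th-order design run
forward and backward (effective 8th-order magnitude). The filters use
steady-state initial conditions plus odd-reflection padding, so a constant
offset produces no edge ringing; zero phase means conditioning introduces
no relative delay between signals — a property the test suite asserts at
sample resolution. The raw summed binary train enters conditioning
directly; the 2-Hz lowpass is its smoothing.

**Windowed cross-correlation and delays.** Conditioned signal pairs are
compared in fully contained 5-s windows with 50 % overlap (a 30-s plateau
gives exactly 11 windows). In each window the Pearson correlation is
recomputed at every integer-sample lag over the overlapping samples; the
window's coefficient is the maximum and its delay the argmax, with no
sub-sample interpolation (0.49 ms resolution at 2048 Hz is far below the
~75–150 ms effects). Exact ties resolve to the smallest |lag|; positive lag
means the first-named signal leads. Reported values are arithmetic means
over windows. Two estimator rules matter in practice:

* *Search range.* The band correlation is quasi-periodic with lobes about
  0.8 s apart, so a ±1 s search admits period-ambiguous sidelobes, and any
  excess range lets rare spurious noise peaks drag the arithmetic mean lag
  toward zero. Pipeline analyses search ±350 ms — just above the largest
  physiological delay (< 300 ms) and far below the band period. The
  function default remains ±1 s and both are configurable.
* *Boundary peaks.* A window whose maximum falls exactly on the search
  boundary has not resolved an interior peak; such windows are failed
  detections and are skipped (and counted), like zero-variance windows.
  Without this rule rare boundary hits dominate the mean lag.

**Fascicle tracking.** Fascicle geometry is tracked by pyramidal
Lucas–Kanade affine optical flow (Gauss–Newton on the sum of squared
intensity differences, 3 pyramid levels, convergence at an update of
10^-3 px). Frame-to-frame transforms are composed to carry the frame-0
endpoints and aponeurosis line through the sequence; drift is accepted and
measured against synthetic ground truth rather than suppressed by
re-anchoring. The flow region is the dilated fascicle bounding box
(20 px margin) clipped a few pixels above the aponeurosis, whose echo does
not follow fascicle motion; frames are pre-blurred by 1 px before
differentiation, which suppresses the sub-pixel interpolation bias that
otherwise accumulates over a thousand compositions. Length is the endpoint
distance times the pixel scale (field of view ÷ image width); pennation is
the acute angle to the aponeurosis; shortening is rest length minus current
length (rest = frame 0, overridable). Per-frame traces are placed at their
trigger-edge samples and cubic-spline interpolated to 2048 Hz.

**Thresholds in two coordinate systems.** Contractions are segmented into
ramp-up / plateau / ramp-down: onset at 2 %MVC sustained 100 ms, plateau as
the longest run within ±25 % of target with a 500-ms-smoothed slope below
2 %MVC/s (the ±25 % band admits the sinusoidal mode in the same code
path; sub-second criterion dropouts are bridged so fluctuation excursions
do not fragment the plateau; with `smooth_ms = 0` the segmentation of a
noiseless trapezoid is exact). Each unit's recruitment values are read at
the sample of its first discharge and de-recruitment values at its last —
no local averaging — in both %MVC torque and Δ fascicle length.

**Group level.** "Subjects" are simulation seeds with ±10 % jitter on rest
length, delays and MVC torque. Tables are aggregated per subject and
contrasted pairwise: mean difference, 95 % CI from the t distribution, and
two-sided paired-t probability; marginal effects collapse balanced designs
over the other factor first. With a single row per cell (contrasting
printed group means) the difference is still defined and the CI/p are NA.
Omnibus repeated-measures ANOVA is deliberately not part of the package's
claims; contrasts with CIs are.

## The synthetic experiment

**Motoneuron pool.** Seven units (the typical per-participant yield in
this kind of recording) with recruitment excitations on an exponential
ladder spanning a 30-fold range, the highest placed at 15 %MVC of drive so
the whole pool is active below a 20 %MVC target. Rate coding is linear:
8 Hz at recruitment, 0.46 Hz per %MVC (chosen in closed form so the pooled
plateau mean at 20 %MVC is ≈15 Hz), saturating at 35 Hz. Discharges are
renewal processes with multiplicative Gaussian interval jitter (CV 0.15,
floored at 0.1 of the mean interval). Sampling uses time rescaling — the
instantaneous rate is integrated and a spike emitted at jittered unit-area
crossings — which reproduces the classic "interval = jitter/rate" rule
exactly under constant drive but lets the discharge rate follow the
excitation instantaneously; the naive sequential rule reads the rate one
interval late, which measurably biases delay estimates built on these
trains. The first spike of each recruitment episode falls on the threshold
crossing. An optional de-recruitment hysteresis (`derecruit_frac`) lets
units keep firing below their recruitment excitation, as persistent inward
currents do in vivo; it is off by default.

**Common drive.** The excitation is the commanded trapezoid (or
trapezoid-with-sinusoid) plus a shared band-limited fluctuation (default
SD 1.5 %MVC, shaped to 0.4–2.5 Hz, scaled down along the ramps and absent
at rest). This is the component that makes neural drive, fascicle length
and torque co-fluctuate at all; its amplitude is calibrated so the
band-limited CST–torque correlation of a default trial sits near the
≈0.7 reported for voluntary dorsiflexion. The mechanics transduce this
whole-pool drive rather than the 7 detected units' summed train: in vivo
the renewal noise of the many undetected units averages out, and driving
the muscle from a 7-unit CST would make torque about five times rougher
than real force-steadiness data. (A spike-driven mechanics path remains
available, with a 400-ms zero-phase Hann smoothing standing in for twitch
fusion.)

**Mechanics.** Fascicle length is `rest − A·s(t − Δf)` and torque
`B·s(t − Δf − Δt)`, with Δf = Δt = 75 ms by default — so drive→fascicle is
~75 ms and drive→torque ~150 ms — implemented as pure integer-sample
shifts, making the injected latencies exact ground truth for the lag
estimators. A and B are calibrated so a sustained 20 %MVC plateau produces
the configured shortening (7.5 mm at the short length; 8.2 mm long) and
%MVC torque equal to the drive. Pennation is affine in shortening between
its rest and 20 %MVC anchors (15.2°→19.2° over 7.5 mm at the short
length). Measurement noise is band-shaped (below 5 Hz): 0.3 %MVC on torque
(a typical force-steadiness scale) and 0.1 mm per frame on fascicle length
(a typical speckle-tracking jitter); white noise at 2048 Hz would carry
almost no power into the 0.75–2 Hz analysis band and would make the
coefficients unrealistically high. An alternative `"causal-kernel"` mode
replaces the shifts with a critically damped kernel `(t/τ²)e^{−t/τ}`
(τ = delay/2 per stage) for realism; its band-limited group delay must
then be measured, not assumed.

**EMG and ultrasound.** The EMG is a linear superposition of per-unit
spatio-temporal templates (Gaussian-windowed oscillations with per-channel
decay and per-row latency over the 8×4 grid) placed at every discharge,
plus white noise — enough structure for spike-triggered averaging and
2-D template matching to be exercised exactly. The renderer draws each
frame from a single static speckle background warped by the affine that
carries the frame-0 fascicle segment onto the commanded frame-k segment
(fixed insertion, length scaling along the fascicle, rotation to the
commanded pennation), then overlays the fascicle and aponeurosis as bright
lines; the commanded geometry is therefore exactly encoded in the drawn
endpoints, and affine flow has a recoverable ground truth. One rising
trigger edge is emitted per frame. A master seed fans out into named
sub-streams (drive, spikes, mechanics noise, templates, EMG noise,
speckle), so any component can be varied independently and a whole trial
is reproducible bit for bit.

What the generator does **not** emulate: volume-conductor EMG physics,
decomposition errors (spike trains are the generator's own), out-of-plane
fascicle motion, probe pressure and skin movement artefacts, tremor
peaks, fatigue, or feedback torque matching (the drive is open loop).
Passing tests therefore show that the analysis recovers what this model
injects — not that it is robust to every artefact of real recordings.

## Numerical choices and edge cases

* Zero-phase filtering uses steady-state initial conditions; without them
  a DC offset rings for seconds at a 0.75 Hz corner.
* Mean discharge rate is `(n−1)/span` over the window, unbiased for sparse
  trains; fewer than two discharges give 0. Rate traces use a unit-area
  400-ms Hann kernel — wide enough to be smooth, narrow enough to resolve
  the 0.5-Hz sinusoidal target.
* Refractory cleaning keeps the *first* spike of a duplicate cluster — the
  deterministic replacement for what an operator resolves by eye.
* A textureless flow region (singular normal matrix) returns the identity
  transform with a failure flag; tracking carries the previous geometry
  forward and flags the frame.
* Degenerate paired contrasts (zero-variance differences) short-circuit to
  p = 1 and a [0, 0] interval rather than dividing by zero.
* The SIL of a source whose candidate peaks are all equal is defined as 0.

## Known limitations, and one deliberate red flag

Two spec-level expectations are *not* met by the faithful model, and we
keep them visible rather than engineering around them:

* **Torque-coordinate threshold asymmetry has the opposite sign to the
  in-vivo observation.** With a causal fascicle→torque delay, torque lags
  the drive; on the rising ramp the torque read at a unit's first
  discharge is *lower* than its drive threshold, and on the falling ramp
  the torque at its last discharge is *higher* — so de-recruitment torque
  thresholds exceed recruitment thresholds by about `2·slope·delay`
  (~1.5 %MVC at Δt = 75 ms plus up to one inter-spike interval of ramp
  travel). Human data show the opposite ordering, which requires
  motoneuron de-recruitment hysteresis (persistent inward currents) and/or
  a hysteretic drive–force gain — mechanisms outside this generator's
  scope. The Δ-fascicle-length coordinate, by contrast, is symmetric as
  observed in vivo (within 0.5 mm when Δf = 0). Setting
  `poolConfig(derecruit_frac = 0.6)` demonstrates how hysteresis flips the
  torque-coordinate ordering; it is off by default.
* **Exact zero-delay threshold symmetry is unattainable with renewal
  firing**: the last discharge precedes the falling threshold crossing by
  up to one inter-spike interval, ≈0.6 %MVC of ramp travel on average.
  Symmetry is asserted at that renewal resolution.

## Problem sizes

The shipped tests and the acceptance script run the generator at the
protocol's native rates (2048 Hz, 80 fps) with 10-16 simulated subjects
for delay and threshold recovery, 30-s plateaus for windowing and delay
estimation, 10-s plateaus for threshold runs, and an 8-s rendered trial
(640 frames, 256×128 px) for optical-flow verification; the cohort
pipeline example uses 12-s plateaus. These sizes give stable Monte-Carlo
estimates while keeping a full run in the minutes range on one core.
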