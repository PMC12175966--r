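---
title: "Methods: quantifying rotational-resistance effects on motor-cortex activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying rotational-resistance effects on motor-cortex activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(untether)
```

## The problem

A mouse carrying a head-mounted two-photon fiberscope is tethered by an
optical fiber. When the animal turns, the fiber twists and a restoring
torque builds up; unless it is cancelled, the animal works against it with
every rotation. `untether` implements the analysis chain for asking how
much this rotational resistance matters — behaviorally and neurally — and
a simulator for the proactive commutator that removes it.

Four conditions grade the resistance: `free` (no resistive tether), `on`
(tether with active torque compensation), `off` (compensation disabled, so
the tether resists), and `fixed` (head-fixed on a platter; the head cannot
rotate at all). Sessions default to 1000 imaging frames at 3 frames/s
(333 s) in a 25.4 cm (10-inch) square arena.

## Behavioral kinematics

`compute_kinematics()` works on point trajectories (time, x, y). Walking
distance is the summed frame-to-frame Euclidean displacement. Heading is
the direction of each displacement vector; displacements below
`min_displacement` (default 0.2 cm) carry no heading information and are
skipped, which suppresses tracking jitter when the animal is still — pose
tools report sub-millimetre wobble on a resting animal that would
otherwise accumulate into spurious turning. Heading increments are wrapped
into (−π, π] before absolute summation, so the turning angle measures
total rotation in either direction, not net rotation: an animal that turns
hundreds of radians in a session does so by many full turns, which a
signed sum would cancel. Linear speed uses central differences (one-sided
at the ends).

Locomotion is segmented by the 1 cm/s speed threshold. Runs of either
state shorter than `min_bout` (default 1 s) are absorbed into their
surroundings — shortest run first, earliest on ties — because a
single-frame dip below threshold at 3 frames/s is sampling noise, not a
rest. For head-fixed sessions the same rule applies to the platter's
angular speed after converting the threshold through an effective radius
(default 10 cm, the assumed distance of the paws from the rotation axis;
the true platter geometry is an apparatus property the analyst should
supply).

Condition summaries report per-condition means and percent changes
`(mean_A − mean_B)/mean_B × 100`, truncated to integer percent —
truncation, not rounding-to-nearest, is the rule consistent with the
published summary figures this operation reproduces. `bonferroni()` is the
standard post-hoc adjustment `min(1, m·p)`.

## Event detection and the fluorescence rate

The unit of neural activity here is one calcium firing event in a ΔF/F
trace, scored by the fluorescence rate **r = ΔS/Δt**: the area under the
firing peak divided by its duration, i.e. the mean baseline-subtracted
ΔF/F over the event. This makes r a per-event intensity with ΔF/F units,
comparable across conditions with different event counts.

Detection is deliberately simple and explicit rather than model-based
deconvolution: the statistic is defined directly on the ΔF/F trace, so
events are delimited on it. Steps and defaults:

- **Baseline**: rolling 8th percentile over a 30 s window. A low
  percentile of pure noise sits `σ·qnorm(0.08) ≈ 1.4σ` below the true
  baseline, so that Gaussian bias is added back; on transient-free noise
  the corrected baseline is centred on zero.
- **Noise**: `σ = 1.4826 × MAD(dff − baseline)` — robust to the sparse
  transients riding on the baseline.
- **Thresholds**: an event opens at `dff − baseline ≥ 2.5σ` and closes
  below `0.5σ` (hysteresis avoids chatter around one threshold). Events
  closer than one frame merge; events shorter than 2 frames are dropped.
  Noiseless traces (σ = 0) fall back to an absolute opening threshold
  (default 0.1 ΔF/F).
- **Quadrature**: ΔS is the per-frame rectangle sum of the clipped
  (dff − baseline), and Δt the frame count over the frame rate. Clipping
  at zero keeps noise dips from contributing negative area. The rectangle
  rule is chosen over the trapezoid so that the defining identity of r is
  exact on discrete data: a rectangular pulse of height h scores r = h at
  any frame rate. At 3 frames/s the discretisation error on smooth pulse
  shapes is below ~10% (a triangle of peak p scores p/2 within 0.06·p);
  at 12 frames/s individual event areas match the analytic kernel
  integral within 5%.

Because the analysis scores firing during movement, events are gated by
the locomotion mask: an event belongs to locomotion iff its onset frame is
in a locomotion bout (a majority-overlap rule is available). The retained
rates form one set per neuron per condition, pooling sessions of the same
condition; empty sets are kept and flagged rather than dropped.

## Per-neuron comparison and classification

Rate distributions are not normal, so each neuron is tested with a
two-sided Mann–Whitney U test at α = 0.05. The package's implementation
uses midranks for ties and two modes:

- **Exact** (both n ≤ 8, or on request): the full permutation
  distribution of U is computed with a shift-algorithm dynamic programme
  over the doubled midranks, which stays correct under ties; the p-value
  is `P(|U − n_a n_b/2| ≥ |U_obs − n_a n_b/2|)`.
- **Normal approximation** otherwise, with the tie-corrected variance and
  a 0.5 continuity correction.

A significant neuron is *increased* when the direction statistic (U versus
its null mean, falling back to median order on a tie) favours the test
condition, *decreased* otherwise; non-significant neurons, and neurons
with fewer than `min_events = 3` events in either condition, are *other*.
Direction is assigned post hoc to a two-sided test, matching the symmetric
increased/decreased classes. No correction across neurons is applied by
default — the per-neuron tests are reported at 0.05 — with
Benjamini–Hochberg available as an option.

Consistent-trend neurons shift the same way in both the off-vs-on and
fixed-vs-on comparisons. The primary definition requires significance in
both; a `median_order` option relaxes this to the ordering of condition
medians, since a plausible alternative reading of "consistently increased"
requires only that. Proportion summaries give the stacked percentages of
the three labels per comparison.

## The commutator simulator

The control loop is simulated in discrete time. The tether is a linear
torsional spring: twist φ = heading − commutator angle, torque τ = k·φ.
Each tick the sensed torque (τ plus optional Gaussian sensor noise) is
compared with the activation threshold (default 0.8 mN·m); when reached,
the stepper issues microsteps of 0.225° in the torque's direction until
the recomputed |τ| falls below threshold or the per-tick budget
`max_step_rate · sim_dt` runs out. With compensation off the commutator
never moves.

Design choices where the hardware description leaves freedom:

- **Stiffness** is not a published quantity; the default 2 mN·m/rad is
  chosen so a few degrees of twist reach the 0.8 mN·m threshold, the same
  scale at which passive commutators become perceptible to a mouse. It is
  an explicit config parameter, not a constant.
- **Latency**: the stepper driver responds in ~1.2 µs, far below the 1 ms
  tick, so compensation is modelled as instantaneous within a tick (the
  config still validates latency ≤ tick).
- **Hysteresis**: stepping stops at the same threshold that starts it; the
  loop description mentions a single threshold. Consequently the residual
  twist after compensation is just under threshold/stiffness (~0.4 rad at
  defaults) — the commutator tracks the animal to within that band, not
  to within one microstep.
- **Recorded torque** is the post-compensation value each tick — the
  torque the animal sustains over the tick; the sub-millisecond transient
  above threshold during stepping is below the loop's time resolution.
- The sensor's 0.2 mN·m sensitivity is represented as optional Gaussian
  sensor noise (off by default).

Two invariants anchor the simulator: with compensation off the spring law
is exact (five turns of a k = 2 mN·m/rad tether end at 2·10π ≈
62.8 mN·m), and with compensation on the sustained torque never exceeds
threshold + k·(one microstep) for slow ramps, with the on/off ratio of
rotational work (∫τ dθ) around 2.5% on the default five-turn scenario.
`torque_from_force()` converts a limb force and lever arm to torque —
about 1.5 gram-force at a 54 mm arm reaches the 0.8 mN·m threshold.

## The synthetic-data generators

No public recordings accompany this analysis, so the package generates its
own data with known ground truth; every downstream claim the tests make is
a claim about recovery of that ground truth.

- **Traces** (`generate_dff()`): per-neuron events are a homogeneous
  Poisson process (default 6 events/min under "on"), convolved with a
  double-exponential kernel (rise 0.1 s, decay 0.6 s — GCaMP6m-like,
  configurable since indicator kinetics vary with expression), unit peak,
  plus i.i.d. Gaussian noise (default σ = 0.05 ΔF/F). Events are placed
  inside locomotion bouts by default, because the analysis scores firing
  during locomotion; uniform placement is a flag. The condition gain
  multiplies both the event rate and the transient amplitude: a gain on
  rate alone would change how often a neuron fires but not the per-event
  statistic r, leaving the ground-truth labels undetectable by
  construction; modelling stronger drive as more frequent *and* larger
  transients makes the labels meaningful for the r-based classification.
- **Trajectories** (`generate_trajectory()`): a correlated random walk —
  exponential step lengths (mean 3 cm/s under "on", the scale of normal
  open-field locomotion; lower under "off"), wrapped-normal heading
  increments with sd `1/sqrt(turn_concentration)` (a von Mises would be
  interchangeable at these concentrations). Walls reflect both position
  and heading, so the walker neither leaves the arena nor grinds against
  a wall.
- **Platter** (`generate_platter()`): rest/locomotion bout schedules with
  angular velocity near zero or near a set point, plus noise; the bout
  boundaries are kept as ground truth for the segmentation tests.
- **Rate sets** (`generate_rate_sets()`): an event-level shortcut drawing
  r values directly from a log-normal (sdlog 0.5) scaled by the condition
  gain — used for the statistical calibration experiments (type-I error,
  power, recovery) where simulating thousands of full traces would add
  nothing but runtime.

What the generators do *not* emulate: overlapping transients from bursts,
photobleaching and slow baseline drift, motion artefacts, neuropil
contamination, or any spatial structure. Passing tests therefore
demonstrate that the pipeline recovers known effects under clean
conditions — they do not certify performance on raw imaging data, whose
preprocessing (motion correction, segmentation, denoising) is out of scope
here.

Every stochastic function takes an explicit integer seed and uses no
global RNG state; identical seed and parameters give bit-identical output.
`run_pipeline()` derives per-stage seeds from one master seed by fixed
offsets.

## Problem sizes and calibration experiments

The test suite and the acceptance script use: 2000 random instances (set
sizes ≤ 6) against the enumeration oracle and one 10⁵-resample permutation
comparison at n = 30 for the Mann–Whitney implementation; 1000 null
neurons (30 events per condition) for the type-I error rate, which should
sit within two Monte-Carlo standard deviations of 0.05; and 400 affected
neurons (gains 2.0 and 0.5, 30 events per condition) for label recovery,
expected above 90% — at those gains the rate distributions are separated
by 1.4 log-sd, so the test is comfortably powered. End-to-end trace-level
runs use smaller cohorts (tens of neurons, 400–1000 frames), which
exercise every stage of the chain at full fidelity.

## Known limitations

- Event delimitation by threshold crossing will merge genuinely
  overlapping transients and undercount during bursts; the fluorescence
  rate of a merged event is a duration-weighted mean.
- The turning-angle estimator is bounded by π per frame; very fast
  rotations at 3 frames/s alias.
- The bout-merging rule is greedy (shortest-first); pathological
  alternating speed series collapse to a single state, which is the
  intended reading of a series with no run longer than the minimum bout.
- The simulator's control rule is a faithful reading of the loop
  description, not of the device firmware; burst stepping, debouncing or
  direction logic in the actual controller could differ in detail.
- The mixed-effects modelling used for the published behavioral group
  statistics is not reimplemented; the package reports descriptive
  summaries, percent changes and Bonferroni adjustment.
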