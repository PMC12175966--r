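# untether

Head-mounted miniature microscopes tether an animal to its instrumentation.
As the animal turns, torque builds in the fiber tether and resists further
rotation — a subtle constraint that can change both behavior and the neural
activity being recorded. `untether` is an R package for quantifying that
effect and for simulating the engineering remedy: a proactive
optoelectrical commutator (pOEC) that senses tether torque and rotates the
fiberscope to cancel it before the animal feels resistance.

The package covers four experimental conditions used to grade rotational
resistance: `free` (untethered or freely rotating), `on` (tether with
active torque compensation), `off` (compensation disabled), and `fixed`
(head-fixed on a rotating platter, the extreme case).

## What it computes

**Behavior.** From 2-D arena trajectories: walking distance, total turning
angle (absolute heading change, wrapped into (−π, π]), and per-frame linear
and angular speed. Locomotion and rest are segmented with a 1 cm/s velocity
threshold; for head-fixed sessions the same threshold is applied to the
platter's angular velocity via an effective radius. Condition summaries
report per-condition means and integer percent changes.

**Calcium activity.** Firing events are detected in ΔF/F traces by
threshold crossing over a rolling-percentile baseline, and each event is
scored with the fluorescence rate

> r = ΔS / Δt,

the area under the firing peak divided by its duration — the mean
baseline-subtracted ΔF/F over the event. Events are restricted to
locomotion periods, and each neuron's rates under one condition form a set
(R_on, R_off, R_fixed).

**Classification.** Per neuron, rate sets are compared across conditions
with a two-sided Mann–Whitney U test (enumeration-exact for small sets,
tie- and continuity-corrected normal approximation otherwise) at α = 0.05.
Neurons are labelled *increased*, *decreased*, or *other*, and neurons
shifting the same way in both the off-vs-on and fixed-vs-on comparisons are
flagged as consistent-trend (R_off > R_on and R_fix > R_on, or both
reversed).

**Simulation.** A discrete-time closed loop models the commutator: a
torsional-spring tether (τ = k·φ), a 0.8 mN·m activation threshold, and
0.225°-microstep compensation that unwinds the twist whenever the sensed
torque reaches threshold. Synthetic generators produce GCaMP6m-like ΔF/F
traces, correlated-random-walk arena trajectories, and platter rotation
traces with known ground truth, so every stage is testable end to end.

## Worked example

```r
library(untether)

cfg <- run_config(seed = 1L, n_neurons = 40L,
                  frac_increased = 0.2, frac_decreased = 0.2)
rep <- run_pipeline(cfg)
rep
#> <untether_report: 40 neurons; 2375 events; 8/8 consistent up/down>
rep$proportions
#> # A tibble: 6 × 4
#>   comparison  label         n percent
#>   <chr>       <fct>     <int>   <dbl>
#> 1 fixed_vs_on increased     8    20
#> 2 fixed_vs_on decreased     8    20
#> 3 fixed_vs_on other        24    60
#> 4 off_vs_on   increased     9    22.5
#> 5 off_vs_on   decreased    10    25
#> 6 off_vs_on   other        21    52.5
```

Here 20% of the cohort was generated with its activity doubled under
"off"/"fixed" and 20% halved; the classifier recovers 8/8 of each marked
subset as consistent-trend neurons, with a few null neurons crossing the
5% significance line as expected.

The commutator simulation contrasts a locked tether with active
compensation over five full turns at 0.5 turn/s:

```r
glance(simulate_poec(heading_ramp(), poec_config()))
#>   compensation total_steps max_abs_torque_mNm rotational_work_uJ final_twist_rad
#> 1         TRUE        7899          0.7995353           24862.13       0.3966261
```

With compensation the tether torque never exceeds the 0.8 mN·m threshold
(a locked tether would reach k·10π ≈ 62.8 mN·m), and the rotational work
the animal performs drops to about 2.5% of the locked case.

Plots: `autoplot()` on kinematics and simulation objects,
`plot_condition_boxes()`, `plot_classification_proportions()`, and
`plot_trend_medians()` mirror the figures practitioners expect
(trajectory maps coloured by angular speed, stacked label bars, per-neuron
median-rate trends).

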