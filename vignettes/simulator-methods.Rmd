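---
title: "Simulator methods: plant, outflow logic, controller and metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulator methods: plant, outflow logic, controller and metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resusim)
```

`resusim` is a software analogue of a benchtop flow-loop testbed for
closed-loop hemorrhage-resuscitation controllers. A controller under test
observes a windowed mean arterial pressure (MAP) and commands an infusion
pump; the simulator supplies everything else — a pressure–volume plant,
an automated hemorrhage/urine outflow engine, scripted adverse events,
and a standardized twelve-metric performance report. This vignette
documents the model, its parameters and units, the numerical choices, and
what the shipped defaults do and do not emulate.

## The hydrostatic pressure–volume plant

The plant is a hydrostatic reservoir ("vessel") elevated above a
circulation loop. Because the pressure at the vessel port equals the
height of the water column above it, a vessel's *shape* encodes an
arbitrary monotone MAP-vs-volume relationship. Given a target curve
$P(V)$ (mmHg as a function of infused mL), `design_vessel_from_curve()`
inverts it to $V(P)$, substitutes height for pressure through the
hydrostatic relation $z = P \cdot h$ (with $h = 13.595$ mm of water per
mmHg, water near 4&nbsp;°C; configurable for other working fluids), and
recovers the radius profile

$$ r(z) = \sqrt{\frac{1}{\pi}\,\frac{dV}{dz}}. $$

A linear curve yields a right cylinder; a parabolic curve with stiffness
$dP/dV$ decreasing in volume yields a funnel whose radius grows with
height.

Two default curves are shipped:

* **Whole blood** — linear, with slope fixed so the designed cylinder has
  an equivalent radius of exactly 27&nbsp;mm, i.e. 31.14&nbsp;mL per
  mmHg. This pins the plant's compliance to the physical vessel the
  design targets.
* **Crystalloid** — parabolic, $P = 0.034V - 2.4\times10^{-6}V^2$ over
  0–90&nbsp;mmHg, reaching the 68&nbsp;mmHg resuscitation target near
  2410&nbsp;mL with stiffness decreasing in volume. The swine regression
  coefficients behind the original vessels are not publicly deposited,
  and the printed closed-form radius formula for the crystalloid vessel
  is typographically ambiguous in the source material, so the package
  does not hard-code it: crystalloid geometry is always derived from a
  configurable curve. The shipped coefficients were chosen once so that
  the crystalloid vessel is moderately less stiff than whole blood near
  the target and spans the working pressure range.

Subject variability multiplies the equivalent radius
(`apply_subject_variation()`); volume at every pressure scales with the
square of the factor.

**Numerics.** Contained volume is a composite-trapezoid integral of
$\pi r(z)^2$ on a fixed 0.1&nbsp;mm height grid, and the profile's P–V
map is *defined* as linear interpolation of that cumulative sum. The
inverse lookup interpolates the same table with the axes swapped, so
`pressure_at_volume()` and `volume_at_pressure()` are exact inverses up
to floating point — the round-trip property the tests assert at
$10^{-5}$&nbsp;mmHg. For a cylinder the trapezoid rule is exact, which is
what lets the test suite compare against the closed form at
$10^{-9}$ relative error.

## Waveform, sensing and the vasopressor branch

The circulating pump adds a pulsatile component, modelled as a pure
cosine at 120 beats/min with a default 10&nbsp;mmHg peak-to-trough
amplitude (the source rig reports a 2&nbsp;mL stroke volume at
120&nbsp;BPM; the pulse amplitude at the pressure tap is not reported and
is a free parameter). A cosine was chosen over a shaped ejection pulse
deliberately: it is exactly zero-mean over whole beats under both
continuous integration and uniform discrete sampling, so the sensed MAP
is provably independent of the pulse — the property the plant tests
check at $10^{-9}$&nbsp;mmHg.

The sensed MAP supplied to controllers and to the outflow logic is the
time-weighted (trapezoid) average of the raw waveform over a trailing
5&nbsp;s window.

The vasopressor is an additive pressure step (default exactly
15.0&nbsp;mmHg) toggled by `set_vasopressor()`. In the physical rig it is
a resistance branch; since loop flow is constant in the simulator a
resistance-times-flow product is indistinguishable from an additive step,
so the simpler model is used, with magnitude and duration configurable.

Volume integrates by explicit Euler at 0.1&nbsp;s. At a maximum net flow
of 600&nbsp;mL/min this moves at most 1&nbsp;mL (≈ 0.03&nbsp;mmHg) per
step, far below the sensing resolution; the conservation tests bound the
bookkeeping error at $10^{-3}$&nbsp;mL over a full four-scenario run.
Reservoir boundaries clamp with a logged `starved`/`overflowed` flag
rather than failing, matching a physical tank.

## The outflow engine

Total outflow is hemorrhage plus urine, driven by one pump with a
combined clamp of 0–600&nbsp;mL/min.

* **Hemorrhage** is $\mathrm{MAP} \times HF$, where the hemorrhage
  factor $HF$ (mL/min per mmHg) is the scenario's severity dial. The
  high- and low-severity initializations are $120/68$ and $60/68$,
  producing 120 and 60&nbsp;mL/min at the 68&nbsp;mmHg target. Each
  1&nbsp;s update perturbs the rate by multiplicative uniform noise of
  ±5%.
* **Low-MAP shutoff**: below 30&nbsp;mmHg bleeding is treated as
  negligible and the rate is zero.
* **Coagulation** decays $HF$ exponentially while MAP stays in the
  neutral band (30–70&nbsp;mmHg). The decay *form* is a modelling choice
  (the source only requires a gradual, infusate-dependent reduction);
  exponential decay with rates 0.05/min (whole blood) and 0.02/min
  (crystalloid) gives clot consolidation half-times of roughly 14 and
  35&nbsp;min.
* **Over-pressure penalty**: above 70&nbsp;mmHg $HF$ grows at
  0.05/min (clots dislodging), and more than 2&nbsp;mmHg above the
  threshold the clotting timer is reset. The two thresholds are kept
  separately configurable because the source describes the escalation
  at 70 and the reset margin at +2 in different places.
* **Urine** runs at a fixed basal 5&nbsp;mL/min once MAP is at or above
  50&nbsp;mmHg (inclusive), zero below. Noise applies to the hemorrhage
  product only.
* **Events**: `massive_hemorrhage` immediately imposes $HF = 255/68$
  (255&nbsp;mL/min at target — on the order of resting femoral artery
  flow); `ramp_to_cap` switches to a monotone escalation toward a
  user-defined ceiling with coagulation suppressed, modelling
  trauma-induced coagulopathy.

## The reference controller

The reference controller is a six-step decision table: the error
$e = \mathrm{MAP_T} - \mathrm{MAP}$ selects a fraction of the pump
maximum $Q_{max} = 500$&nbsp;mL/min (the characterization infusion rate,
aligned with the pump's ceiling):

| error (mmHg)  | fraction of $Q_{max}$ |
|---------------|----------------------|
| ≥ 25          | 1.00 |
| [15, 25)      | 0.60 |
| [10, 15)      | 0.40 |
| [5, 10)       | 0.30 |
| [0.5, 5)      | 0.25 |
| < 0.5         | 0 |

The numeric bands of the original instrument are not legible from the
source, so this table is a design choice, fully overridable in
configuration. Two constraints shaped it. First, the lowest non-zero
band must reach within $0.01 \cdot \mathrm{MAP_T}$ of the target:
scenarios terminate only after the sensed MAP attains 99% of the target,
so a controller whose dead band starts at a 2&nbsp;mmHg error parks just
below the threshold and can never finish. Second, the near-target rates
are large enough that a rate held for a 120&nbsp;s sampling period
overshoots the 70&nbsp;mmHg penalty threshold while the same rate
re-evaluated every 5&nbsp;s does not — the sampling-rate contrast the
testbed exists to expose. Output is held constant between sampling
instants (zero-order hold), with the first update at $t = 0$.

## Scenarios

Four scenarios run in succession with carried-over state (an optional
`reset_baseline` mode re-initializes to 40&nbsp;mmHg between scenarios):

1. **Initial bleed** — from the hemorrhagic-shock baseline (40&nbsp;mmHg,
   ~2300&nbsp;mL whole-system deficit), whole-blood resuscitation under
   active coagulation.
2. **Tourniquet failure** — a massive re-bleed, then whole-blood
   resuscitation.
3. **Tourniquet failure + vasopressor** — as 2, with a 15&nbsp;mmHg
   bolus applied immediately after the re-bleed releases and withdrawn
   10&nbsp;min later.
4. **Coagulopathy** — a re-bleed followed by an ongoing non-clotting
   bleed, resuscitated with crystalloid after a pressure-continuous
   vessel switch; hard 30&nbsp;min cap.

The opening re-bleed doubles as the scenario's re-initialization: the
experimental protocol begins every scenario at the 40&nbsp;mmHg shock
baseline, so infusion is suspended while the event is active and the
event releases when the sensed MAP reaches 40&nbsp;mmHg. A maximum event
duration (10&nbsp;min) is kept as a safety valve for controller
configurations that would otherwise hold the pressure up indefinitely.
Scenarios 1–3 finish 15&nbsp;min after the sensed MAP first reaches 99%
of the target during resuscitation, with a 60&nbsp;min safety cap;
scenario 4 always runs 30&nbsp;min.

The scenario-4 escalation is deliberately severity-dependent. The
low-severity bleed ramps from 0.4 to a 0.5&nbsp;mL/min/mmHg cap — about
34&nbsp;mL/min near target, a bleed the controller can outrun. The
high-severity bleed ramps from 2.5 at 0.6/min toward a ceiling of 17:
within the window the hemorrhage comes to exceed the infusion pump's
maximum rate at every attainable pressure. That is the defining feature
of the scenario — an exsanguinating coagulopathic hemorrhage that no
infusion-only controller can arrest — and it is what produces the
diverging, steady-state-free pressure trace the scenario is meant to
elicit. Gentler escalations are less interesting as a stress test: the
banded controller simply pins the pressure at an off-target plateau.

## Performance metrics

All metrics derive from the performance error
$PE_i = (P_i - P_T)/P_T \times 100$:

* **MDPE** (bias), **MDAPE** (accuracy), **wobble** (median absolute
  deviation of $PE$ about MDPE) — medians, with the even-count
  convention of the midpoint of the central pair.
* **Divergence** — 60 × the least-squares slope of $|PE_i|$ against time
  in minutes, in %/h; evaluated as the closed-form slope and
  cross-checked in the tests against an independent `lm()` fit.
* **Steady state** — the value estimate is the mean of the final 10% of
  samples; the onset is the earliest sample after which the trace stays
  within ±5% of that value; no steady state is reported if even the
  final sample leaves the band. The ±5% reference ("5% of what?") is a
  design choice exposed in configuration.
* **Relative overshoot** — maximum pressure above the steady-state
  value, as a percentage of it (the raw mmHg difference is also
  reported); **effectiveness** — percent of run time within ±5&nbsp;mmHg
  of target; **efficiency rise time** — time to first reach 90% of the
  steady-state value.
* **Volume efficiency** — infused / outflow volume; **average infusion
  rate** — mean commanded rate.
* **Area above/below setpoint** — target-normalized areas between the
  trace and the setpoint, in minutes, reported as magnitudes; their
  signed difference equals $\sum PE_i \Delta t_i / 100$ (an identity the
  tests verify). **Rise area** — the below-target area truncated at the
  first sample reaching 90% of target, reported for scenario 1 only
  (later scenarios inherit their starting pressure).

Because the wobble of a run that includes the resuscitation transient
conflates rise and regulation, reports include both the full-scope wobble
and a post-steady-state wobble wherever a steady state was found.

## What the defaults emulate — and what they do not

The shipped defaults reproduce the *logic* of the hardware testbed
exactly (thresholds, rates, event magnitudes, sampling, termination
rules) and its *qualitative dynamics*: a 120&nbsp;s decision-table
controller overshoots into the over-pressure penalty where a 5&nbsp;s
controller does not, and the high-severity coagulopathic scenario defeats
both. They do not reproduce the hardware's quantitative traces: the
swine-derived regression coefficients, the pulse shape at the pressure
tap, and the instrument's exact decision bands are not recoverable from
the source material, and no claim is made that metric values computed
here match those of any physical run. Passing tests demonstrate internal
consistency (conservation, determinism, metric identities) and faithful
logic, not agreement with animal data.

Problem sizes were chosen for a desk-scale suite: full four-scenario
sequences integrate roughly 75–100 simulated minutes at a 0.1&nbsp;s
plant step and complete in a few seconds each; the noise-bound property
uses $10^5$ draws.

## Known limitations

* No pressure-wave propagation, tubing compliance, viscosity or inertial
  effects; the pulse is cosmetic and exactly averages out.
* The vasopressor is a static additive step; cardiac-output effects and
  titration are out of scope.
* Coagulation is a scalar decay on a rate coefficient, not a
  physiological cascade; hematocrit/dilution effects of infusates on
  bleeding are not modelled.
* The reference decision table is a reconstruction, not the original
  instrument's table; comparisons between controllers evaluated *within*
  this simulator are meaningful, absolute values are not calibrated.
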