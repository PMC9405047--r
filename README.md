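# resusim

A software testbed for developing and scoring **closed-loop fluid
resuscitation controllers** under hemorrhagic shock.

Automated goal-directed fluid therapy — an algorithm that watches mean
arterial pressure (MAP) and drives an infusion pump — is hard to evaluate:
animal studies are slow and expensive, and purely in-silico patient models
hide the sampled, noisy, event-driven character of a real test rig.
`resusim` reproduces, in software, a benchtop flow-loop testbed in which a
hydrostatic reservoir's *geometry* encodes the pressure–volume response of
a resuscitation subject, an automated outflow pump bleeds the system
according to pressure-dependent hemorrhage rules, and the controller under
test closes the loop. It is aimed at controller developers who want fast,
reproducible, scriptable evaluation runs with a standardized metric panel
before committing to hardware or animals.

## The model in brief

* **Plant** — a vessel designed from a target MAP-vs-volume curve by
  inverting the hydrostatic column relation: `r(z) = sqrt((1/π) dV/dz)`
  with `z = P × 13.595 mm/mmHg`. Whole blood is linear (a 27 mm-radius
  cylinder, 31.1 mL/mmHg); crystalloid is parabolic (a widening funnel,
  stiffness decreasing with volume). Subject variability scales the
  equivalent radius.
* **Outflow** — hemorrhage = `MAP × HF` (±5% noise), with HF initialized
  at 120/68 (high) or 60/68 (low) mL/min/mmHg, decayed exponentially by
  coagulation, zeroed below 30 mmHg, escalated above 70 mmHg; basal urine
  of 5 mL/min at MAP ≥ 50; scripted massive-hemorrhage (255 mL/min at
  68 mmHg) and non-clotting escalation events.
* **Controller** — a six-step decision table mapping the error
  `MAP_T − MAP` to a fraction of the 500 mL/min pump maximum, re-evaluated
  every 120 s or 5 s with a zero-order hold; any function of
  `(t, sensed MAP) → rate` can be substituted.
* **Scenarios** — four chained tests: initial bleed, tourniquet failure,
  tourniquet failure + 15 mmHg vasopressor bolus, and a 30 min
  coagulopathic crystalloid scenario with a pressure-continuous vessel
  switch.
* **Metrics** — the Varvel panel (MDPE, MDAPE, wobble, divergence in %/h
  from the |PE|-vs-time slope), relative overshoot, effectiveness,
  efficiency rise time, volume efficiency, average infusion rate, and the
  area-above/area-below-setpoint burdens in minutes, per scenario and
  whole-run.

## Worked example

```r
library(resusim)

ctrl <- controller_config(sampling_period = 5)      # 5 s decision cadence
rec  <- run_sequence(default_scenarios("low"), ctrl, seed = 42)

info <- attr(rec, "scenario_info")
for (i in info)
  cat(sprintf("scenario %d: %4.0f s, target reached: %s, over-pressure events: %d\n",
              i$scenario_id, i$duration_s, i$target_reached,
              i$overpressure_events))

rep <- performance_report(rec)
subset(rep, scope == "whole_run")
```

```
scenario 1: 1244 s, target reached: TRUE, over-pressure events: 0
scenario 2: 1499 s, target reached: TRUE, over-pressure events: 0
scenario 3: 1403 s, target reached: TRUE, over-pressure events: 0
scenario 4: 1800 s, target reached: TRUE, over-pressure events: 0
     scope                metric       value  units
 whole_run                  mdpe -0.78777862      %
 whole_run                 mdape  0.78777862      %
 whole_run                wobble  0.25925349      %
 whole_run            divergence -1.91883827    %/h
 whole_run    relative_overshoot  0.43079875      %
 whole_run         effectiveness 70.78500588      %
 whole_run  efficiency_rise_time  3.28333333    min
 whole_run     volume_efficiency  1.13916676  ratio
 whole_run average_infusion_rate 71.07142857 mL/min
 whole_run            area_above  0.00000000    min
 whole_run            area_below  6.99271736    min
 whole_run   steady_state_wobble  0.07339306      %
```

Reading this: the 5 s controller holds the run at a −0.79% median bias
(MDPE) with essentially no drift, never trips the 70 mmHg over-pressure
re-bleed penalty, spends 71% of the whole run (including the deliberate
bleed-down phases) within ±5 mmHg of the 68 mmHg target, and infuses 1.14
mL for every mL lost. Re-running with
`controller_config(sampling_period = 120)` shows the slow controller
overshooting into the re-bleed penalty in every scenario — the contrast
the testbed is designed to expose. `plot_run(rec)` draws the two-panel
pressure/flow figure; `write_outputs(rec, "out/")` writes the record,
report and metadata.

A thin command line lives at `inst/cli/resusim.R`:

```sh
Rscript inst/cli/resusim.R run --bleed high --sample-period 5 --seed 1 --out out/
Rscript inst/cli/resusim.R metrics --csv out/run_record.csv
Rscript inst/cli/resusim.R design-vessel --which crystalloid --out out/
```

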