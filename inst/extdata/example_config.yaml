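# Example resusim run configuration. Every key is optional; omitted
# blocks fall back to the package defaults described in the vignette.
seed: 1
severity: low          # low | high bleed severity
noise: true            # +/-5% multiplicative hemorrhage noise

controller:
  sampling_period_s: 5 # reference configurations: 120 or 5
  q_max: 500           # mL/min
  target: 68           # mmHg
  # bands: list of {lower, fraction}; defaults to the shipped six-step table

outflow:
  urine_rate: 5                # mL/min at MAP >= 50
  map_zero_threshold: 30       # mmHg
  overpressure_threshold: 70   # mmHg
  noise_fraction: 0.05

waveform:
  pulse_rate: 120        # beats/min
  pulse_amplitude: 10    # mmHg peak-to-trough
  stroke_volume: 2       # mL

vessels:
  # wb_curve / crystalloid_curve: {form, coefficients, valid_range}
  # variability_scale: 1.0
  variability_scale: 1.0

start_map: 40            # mmHg shock baseline
deficit_mL: 2300         # initial whole-system volume deficit
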