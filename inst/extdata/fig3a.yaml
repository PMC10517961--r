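# Shannon electrode-safety chart for the 3 mm corneal platinum ring
# electrode (270 um wire), 10 ms phases, 20-400 uA amplitude range.
name: fig3a
cells: []                  # safety analysis only; no field solve
configs: []
durations: []
safety:
  amplitudes: [20, 50, 100, 200, 300, 400]
  phase_ms: 10
  inner_diameter_mm: 3
  wire_diameter_mm: 0.27
  contact_fraction: 1
  k_limit: 1.5
seed: 1
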