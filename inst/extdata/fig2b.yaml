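# Electrode-placement selectivity experiment: TES1 vs TES2 threshold-ratio
# curves for the spiking bipolar cell and the A2 ganglion cell, biphasic
# cathodic-first pulses over the default 0.1-25 ms duration grid.
name: fig2b
grid:
  spacing: 2.0e-4          # m
  domain: [2.0e-2, 2.0e-2, 2.0e-2]
configs: [TES1, TES2]
cells: [bc, rgc]
waveform:
  kind: biphasic
durations: [0.1, 0.3, 1, 3, 10, 25]
search:
  seed: 1000
  tol: 0.02
  dt: 0.01
  cap: 1.0e+9
seed: 1
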