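name: bc
calcium:
  k: 0.00052
  tau: 10.0
  rest: 0.0001
  floor: 1.0e-06
  cao: 1.8
  nernst_factor: 12.7
  erev_fallback: 120.0
channels:
- name: Na
  erev: 35.0
  ca_gate: ~
  carries_ca: no
  gates:
  - exponent: 4.0
    mode: inftau
    f1:
      form: sigmoid
      a: 1.0
      v0: -30.0
      b: 6.0
      c: 0.0
    f2:
      form: gausstau
      a: 4.0
      v0: -30.0
      b: 20.0
      c: 1.0
  - exponent: 1.0
    mode: inftau
    f1:
      form: sigmoid
      a: 1.0
      v0: -52.0
      b: -6.0
      c: 0.0
    f2:
      form: gausstau
      a: 9.0
      v0: -60.0
      b: 25.0
      c: 1.0
- name: Kslow
  erev: -75.0
  ca_gate: ~
  carries_ca: no
  gates:
  - exponent: 2.0
    mode: inftau
    f1:
      form: sigmoid
      a: 1.0
      v0: -28.0
      b: 9.0
      c: 0.0
    f2:
      form: gausstau
      a: 35.0
      v0: -30.0
      b: 30.0
      c: 15.0
- name: Kfast
  erev: -75.0
  ca_gate: ~
  carries_ca: no
  gates:
  - exponent: 1.0
    mode: inftau
    f1:
      form: sigmoid
      a: 1.0
      v0: -20.0
      b: 9.0
      c: 0.0
    f2:
      form: gausstau
      a: 2.4
      v0: -25.0
      b: 30.0
      c: 0.6
- name: CaL
  erev: 120.0
  ca_gate: ~
  carries_ca: no
  gates:
  - exponent: 2.0
    mode: inftau
    f1:
      form: sigmoid
      a: 1.0
      v0: -15.0
      b: 6.0
      c: 0.0
    f2:
      form: gausstau
      a: 2.0
      v0: -15.0
      b: 25.0
      c: 0.5
- name: CaT
  erev: 120.0
  ca_gate: ~
  carries_ca: no
  gates:
  - exponent: 2.0
    mode: inftau
    f1:
      form: sigmoid
      a: 1.0
      v0: -44.0
      b: 5.5
      c: 0.0
    f2:
      form: gausstau
      a: 4.0
      v0: -50.0
      b: 25.0
      c: 1.0
  - exponent: 1.0
    mode: inftau
    f1:
      form: sigmoid
      a: 1.0
      v0: -72.0
      b: -5.0
      c: 0.0
    f2:
      form: gausstau
      a: 60.0
      v0: -70.0
      b: 30.0
      c: 20.0
- name: HCN
  erev: -30.0
  ca_gate: ~
  carries_ca: no
  gates:
  - exponent: 1.0
    mode: inftau
    f1:
      form: sigmoid
      a: 1.0
      v0: -90.0
      b: -7.0
      c: 0.0
    f2:
      form: gausstau
      a: 400.0
      v0: -85.0
      b: 30.0
      c: 80.0
- name: leak
  erev: -60.0
  ca_gate: ~
  carries_ca: no
  gates: []
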