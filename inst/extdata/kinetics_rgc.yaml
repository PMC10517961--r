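name: rgc
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
  - exponent: 3.0
    mode: ab
    f1:
      form: linoid
      a: 0.6
      v0: -30.0
      b: 10.0
      c: 0.0
    f2:
      form: exp
      a: 20.0
      v0: -55.0
      b: -18.0
      c: 0.0
  - exponent: 1.0
    mode: ab
    f1:
      form: exp
      a: 0.4
      v0: -50.0
      b: -20.0
      c: 0.0
    f2:
      form: sigmoid
      a: 6.0
      v0: -20.0
      b: 10.0
      c: 0.0
- name: K
  erev: -75.0
  ca_gate: ~
  carries_ca: no
  gates:
  - exponent: 4.0
    mode: ab
    f1:
      form: linoid
      a: 0.02
      v0: -40.0
      b: 10.0
      c: 0.0
    f2:
      form: exp
      a: 0.4
      v0: -50.0
      b: -80.0
      c: 0.0
- name: KA
  erev: -75.0
  ca_gate: ~
  carries_ca: no
  gates:
  - exponent: 3.0
    mode: ab
    f1:
      form: linoid
      a: 0.006
      v0: -90.0
      b: 10.0
      c: 0.0
    f2:
      form: exp
      a: 0.1
      v0: -30.0
      b: -10.0
      c: 0.0
  - exponent: 1.0
    mode: ab
    f1:
      form: exp
      a: 0.04
      v0: -70.0
      b: -20.0
      c: 0.0
    f2:
      form: sigmoid
      a: 0.6
      v0: -40.0
      b: 10.0
      c: 0.0
- name: KCa
  erev: -75.0
  ca_gate:
    kd: 0.001
    hill: 2.0
  carries_ca: no
  gates: []
- name: Ca
  erev: ca_nernst
  ca_gate: ~
  carries_ca: yes
  gates:
  - exponent: 3.0
    mode: ab
    f1:
      form: linoid
      a: 0.3
      v0: -13.0
      b: 10.0
      c: 0.0
    f2:
      form: exp
      a: 10.0
      v0: -38.0
      b: -18.0
      c: 0.0
- name: h
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
- name: T
  erev: ca_nernst
  ca_gate: ~
  carries_ca: yes
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
- name: leak
  erev: -60.0
  ca_gate: ~
  carries_ca: no
  gates: []
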