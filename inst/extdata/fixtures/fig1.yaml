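model: minimal
params:
  theta_T: 1.0
  beta_T: 0.02
  eps_T: 1.0
  c: 3.0
  eta1: 1.0
  eta2: 1.0
initial_state:
  T: 0.34
settle: no
horizon: 100.0
pulses:
- channel: A
  amplitude: 4.0
  t_on: 5.0
  t_off: 10.0
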