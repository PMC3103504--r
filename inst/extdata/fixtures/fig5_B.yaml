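model: detailed
params:
  beta_T: 0.05
  eps_T: 1.0
  theta_T: 1.0
  k_1a: 1.0
  k_1b: 20.5
  k_1c: 10.0
  k_1d: 1.0
  k_1e: 0.1
  beta_R: 0.05
  eps_R: 1.0
  theta_R: 1.0
  k_2a: 2.1
  k_2b: 0.1
  beta_M: 0.05
  eps_M: 1.0
  theta_M: 1.0
  k_6: 1.0
  k_6b: 1.0
  k_6c: 0.1
  beta_delta: 0.01
  eps_delta: 10.0
  k_3: 1.0
  beta_gamma: 0.01
  eps_gamma: 10.0
  k_4a: 1.0
  k_4b: 1.0
  beta_alpha: 0.01
  eps_alpha: 10.0
  k_5a: 1.0
  k_5b: 1.0
initial_state:
  T: 0.01
  R: 0.01
  M: 0.001
  delta: 0.001
  gamma: 0.001
  alpha: 0.001
settle: yes
horizon: 700.0
pulses:
- channel: A
  amplitude: 100.0
  t_on: 20.0
  t_off: 70.0
- channel: I_delta
  amplitude: 30.0
  t_on: 100.0
  t_off: 120.0
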