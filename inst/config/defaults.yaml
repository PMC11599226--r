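network:
  N_exc: 160.0
  N_inh: 40.0
  N_input: 100.0
  P_in: 0.1
  P_EE: 0.05
  P_EI: 0.02
  P_IE: 0.1
  P_II: 0.0
  dt: 0.0001
  allow_autapses: no
plasticity:
  LR_SDSP: 2.0
  Wmax: 2.0
  LR_thr: 0.025
  Vthr_min: 0.125
  Vthr_max: 0.4
  C_IP: 15.0
  sigma: 0.3
  tau_ip: 0.1
  sdsp_enabled: yes
  ip_enabled: yes
  raw_cfire_compare: no
  ca_increment_before_ip: no
  sdsp_during_refractory: yes
neuron:
  C: 1.0e-11
  R: 4.0e+08
  Vreset: 0.0
  tref: 0.003
  is_excitatory: yes
synapse:
  tau_syn: 0.005
  alpha: 1.2207031e-12
  sign: 1.0
encoding:
  F_poisson: 75.0
  T_bin: 0.15
  dt: 0.0001
  E_min: -2.0
  E_max: 0.5
waveform:
  beat_period: 0.75
  sample_rate: 128.0
  n_beats: 60.0
  baseline: -0.75
  beat_shape:
    center:
    - 0.18
    - 0.36
    - 0.56
    width:
    - 0.025
    - 0.018
    - 0.04
    amplitude:
    - 0.2
    - 1.25
    - 0.35
  anomalies: ~
  noise_sd: 0.02
  seed: 1.0
ridge: 1.0e-06
eps_practical: 0.05
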