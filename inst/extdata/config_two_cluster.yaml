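neuron:
  tau_m_E: 0.02
  tau_m_I: 0.02
  V_th_E: 1.5
  V_th_I: 0.75
  V_r_E: 0.0
  V_r_I: 0.0
  tau_ref_E: 0.005
  tau_ref_I: 0.005
  tau_syn_E: 0.005
  tau_syn_I: 0.005
architecture:
  N_E: 800
  N_I: 200
  p: 2
  f_E: 0.3
  f_I: 0.0
  p_EE: 0.2
  p_EI: 0.5
  p_IE: 0.5
  p_II: 0.5
  J_EE: 0.018
  J_EI: -0.1
  J_IE: 0.025
  J_II: -0.125
  Jplus_EE: 0.09
  Jplus_EI: -0.1
  Jplus_IE: 0.025
  Jplus_II: -0.125
  C_ext_E: 160
  C_ext_I: 160
  J_ext_E: 0.018
  J_ext_I: 0.025
  nu_o_E: 40.0
  nu_o_I: 23.0
notes: >
  Reduced two-cluster network for the effective mean-field theory: two
  excitatory clusters (30 percent of the E population each), an
  unclustered E background and a single I pool; inter-cluster weights are
  not depressed. Calibrated so the unmodulated network is bistable (two
  cluster states joined by an unstable symmetric state) and the barrier
  height decreases with the heterogeneity modulation until the wells
  merge.
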