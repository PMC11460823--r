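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
  N_E: 640
  N_I: 160
  p: 12
  f_E: 0.075
  f_I: 0.075
  p_EE: 0.35
  p_EI: 0.5
  p_IE: 0.5
  p_II: 0.5
  J_EE: 0.018
  J_EI: -0.1
  J_IE: 0.025
  J_II: -0.125
  Jplus_EE: 0.1485
  Jplus_EI: -0.175
  Jplus_IE: 0.04375
  Jplus_II: -0.21875
  C_ext_E: 128
  C_ext_I: 128
  J_ext_E: 0.06
  J_ext_I: 0.08
  nu_o_E: 12.643
  nu_o_I: 6.901
notes: >
  Reduced workhorse architecture (800 neurons, 12 clusters). All values are
  package calibrations, not published measurements: baseline external rates
  solve the uniform-network mean-field equations for target rates of about
  (3, 8) spikes/s; the within-cluster potentiation (ratio 8.25 for E-to-E,
  1.75 for the inhibitory pathways) places the unmodulated clustered
  network in the metastable multi-attractor regime, with cluster states
  degrading over heterogeneity modulations dH_E in [0, 0.4].
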