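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
  N_E: 1600
  N_I: 400
  p: 18
  f_E: 0.05
  f_I: 0.05
  p_EE: 0.2
  p_EI: 0.5
  p_IE: 0.5
  p_II: 0.5
  J_EE: 0.015
  J_EI: -0.06
  J_IE: 0.015
  J_II: -0.075
  Jplus_EE: 0.23625
  Jplus_EI: -0.105
  Jplus_IE: 0.02625
  Jplus_II: -0.13125
  C_ext_E: 320
  C_ext_I: 320
  J_ext_E: 0.015
  J_ext_I: 0.015
  nu_o_E: 27.710
  nu_o_I: 21.575
notes: >
  Full-size architecture (2000 neurons, 18 clusters, one decoding feature
  per cluster plus background). The cluster count, the E-to-E intracluster
  potentiation ratio of 15.75 (so Jplus_EE = 15.75 * J_EE) and the
  heterogeneity-modulation range are the published study conditions; cell
  parameters, baseline weights and external rates are package calibrations
  chosen so the unmodulated network supports coexisting cluster states
  with several active clusters in mean-field.
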