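# Integration of the network dynamics: quiescence, refractoriness,
# determinism, agreement with the diffusion-approximation transfer
# function, integration-step convergence, and the dynamical regimes of the
# uniform and clustered architectures.

test_that("a network without input stays silent and empty runs are allowed", {
  arch <- tiny_arch()
  neuron <- neuron_params()
  inst <- build_uniform(arch, neuron, seed = 1)
  cfg <- sim_config(trial_duration = 0.5, t_stim = 0.4)
  sp <- simulate_trial(inst, rep(0, inst$n), NULL, cfg, seed = 1)
  expect_identical(nrow(sp), 0L)
  ts <- run_experiment(inst, rep(0, inst$n), list(), cfg)
  expect_identical(ts$n_trials, 0L)
})

test_that("no inter-spike interval falls below the refractory period", {
  cfg0 <- default_config("reduced")
  inst <- build_clustered(cfg0$arch, cfg0$neuron, seed = 21)
  nu <- assign_external_rates(inst, arousal_modulation("mean"))
  sp <- simulate_trial(inst, nu, NULL,
                       sim_config(trial_duration = 1, t_stim = 0.9),
                       seed = 4)
  isi_ok <- sp[, .(ok = all(diff(sort(time)) >=
                              cfg0$neuron$tau_ref_E - 1e-9)), by = unit]
  expect_true(all(isi_ok$ok))
  sp2 <- simulate_trial(inst, nu, NULL,
                        sim_config(trial_duration = 1, t_stim = 0.9),
                        seed = 4)
  expect_identical(sp, sp2)
})

test_that("a Poisson-driven isolated neuron matches the transfer function", {
  # single LIF with only background input; mu = J R, sigma^2 = J^2 R.
  # The synaptic correction in the transfer function is a small-tau_s
  # expansion, so the oracle uses a fast synapse and a fine grid step.
  neuron <- neuron_params(tau_syn_E = 5e-4, tau_syn_I = 5e-4)
  for (musig in list(c(64, 1.6), c(72, 2))) {
    mu <- musig[1]; sig <- musig[2]
    J <- sig^2 / mu
    R <- mu^2 / sig^2
    arch <- arch_params(N_E = 1, N_I = 1, p = 1, f_E = 0.5, f_I = 0.5,
                        p_EE = 0, p_EI = 0, p_IE = 0, p_II = 0,
                        J_EE = 0, J_EI = 0, J_IE = 0, J_II = 0,
                        C_ext_E = 1, C_ext_I = 0, J_ext_E = J, J_ext_I = 0,
                        nu_o_E = R, nu_o_I = 0)
    inst <- build_uniform(arch, neuron, seed = 1)
    cfg <- sim_config(dt = 2e-5, trial_duration = 60, t_stim = 59)
    sp <- simulate_trial(inst, assign_external_rates(
      inst, arousal_modulation("mean")), NULL, cfg, seed = 11)
    rate_sim <- sum(sp$unit == 1) / cfg$trial_duration
    rate_th <- transfer_rate(mu, sig, neuron$tau_m_E, neuron$V_r_E,
                             neuron$V_th_E, neuron$tau_ref_E,
                             neuron$tau_syn_E)
    expect_lt(abs(rate_sim - rate_th) / rate_th, 0.1)
  }
})

test_that("halving the integration step changes population rates by < 2 percent", {
  cfg0 <- default_config("reduced")
  arch <- cfg0$arch
  arch$Jplus <- arch$J  # uniform dynamics: stationary rates
  inst <- build_uniform(arch, cfg0$neuron, seed = 5)
  nu <- assign_external_rates(inst, arousal_modulation("mean"))
  r <- sapply(c(0.5e-4, 0.25e-4), function(dt) {
    sp <- simulate_trial(inst, nu, NULL,
                         sim_config(dt = dt, trial_duration = 8,
                                    t_stim = 7.9), seed = 31)
    nrow(sp[sp$unit <= inst$n_E]) / inst$n_E / 8
  })
  expect_lt(abs(r[1] - r[2]) / r[2], 0.02)
})

test_that("the uniform network fires irregularly and asynchronously", {
  cfg0 <- default_config("reduced")
  arch <- cfg0$arch
  arch$Jplus <- arch$J
  inst <- build_uniform(arch, cfg0$neuron, seed = 6)
  nu <- assign_external_rates(inst, arousal_modulation("mean"))
  sp <- simulate_trial(inst, nu, NULL,
                       sim_config(trial_duration = 5, t_stim = 4.9),
                       seed = 8)
  cvs <- sp[, .(n = .N, cv = stats::sd(diff(sort(time))) /
                  mean(diff(sort(time)))), by = unit]
  cvs <- cvs[cvs$n >= 10]
  expect_gt(mean(cvs$cv > 0.7 & cvs$cv < 1.3), 0.6)
  # population rate roughly stationary: compare halves
  r1 <- nrow(sp[sp$time < 2.5]) / 2.5
  r2 <- nrow(sp[sp$time >= 2.5]) / 2.5
  expect_lt(abs(r1 - r2) / r1, 0.2)
})

test_that("the clustered network at baseline shows bimodal cluster rates", {
  cfg0 <- default_config("reduced")
  inst <- build_clustered(cfg0$arch, cfg0$neuron, seed = 9)
  nu <- assign_external_rates(inst, arousal_modulation("mean"))
  sp <- simulate_trial(inst, nu, NULL,
                       sim_config(trial_duration = 3, t_stim = 2.9),
                       seed = 12)
  spE <- sp[sp$unit <= inst$n_E]
  tr <- cluster_rates(spE, inst$cluster_of[seq_len(inst$n_E)],
                      t_range = c(0, 3))
  rates <- tr$rate[tr$clusters <= cfg0$arch$p, ]
  # metastability: both strongly active and nearly-silent cluster epochs
  expect_gt(max(rates, na.rm = TRUE), 30)
  expect_gt(mean(rates < 2, na.rm = TRUE), 0.3)
  expect_gt(mean(rates >= 15, na.rm = TRUE), 0.02)
})
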