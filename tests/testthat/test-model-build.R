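# Network construction: depressed weights, in-degree exactness, arousal
# modulations of the background input, and stimulus sets.

test_that("depressed weight collapses to J when Jplus = J and rejects degenerate fractions", {
  expect_equal(depressed_intercluster_weight(0.03, 0.03, 0.1, 0.2, 5), 0.03)
  expect_equal(depressed_intercluster_weight(-0.08, -0.08, 0.25, 0.25, 3),
               -0.08)
  expect_error(depressed_intercluster_weight(0.03, 0.06, 0, 0, 5),
               "degenerate")
})

test_that("clustered and uniform instances conserve the total summed weight", {
  for (seed in 1:5) {
    arch <- random_exact_arch(seed)
    neuron <- neuron_params()
    wu <- sum(weight_matrix(build_uniform(arch, neuron, seed = seed)))
    wc <- sum(weight_matrix(build_clustered(arch, neuron, seed = seed)))
    expect_lt(abs(wc - wu) / abs(wu), 1e-10)
  }
})

test_that("uniform in-degrees are a point mass at C_ab and seeds reproduce", {
  arch <- tiny_arch()
  neuron <- neuron_params()
  inst <- build_uniform(arch, neuron, seed = 7)
  W <- weight_matrix(inst)
  isE <- inst$pop == "E"
  inE <- rowSums(W[, isE] != 0)
  inI <- rowSums(W[, !isE] != 0)
  expect_true(all(inE[isE] == arch$C["E", "E"]))
  expect_true(all(inE[!isE] == arch$C["I", "E"]))
  expect_true(all(inI[isE] == arch$C["E", "I"]))
  expect_true(all(inI[!isE] == arch$C["I", "I"]))
  expect_true(all(diag(W) == 0))
  inst2 <- build_uniform(arch, neuron, seed = 7)
  expect_identical(inst$syn, inst2$syn)
})

test_that("clustered construction matches the uniform synapse count and weight rules", {
  arch <- tiny_arch()
  neuron <- neuron_params()
  instc <- build_clustered(arch, neuron, seed = 3)
  instu <- build_uniform(arch, neuron, seed = 3)
  # identical number of non-zero synapses
  expect_identical(length(instc$syn$w), length(instu$syn$w))
  # per-cell total in-degree is exact for every (post, pre) pair
  W <- weight_matrix(instc)
  isE <- instc$pop == "E"
  expect_true(all(rowSums(W[isE, isE] != 0) == arch$C["E", "E"]))
  expect_true(all(rowSums(W[isE, !isE] != 0) == arch$C["E", "I"]))
  # every within-cluster E-to-E weight equals Jplus_EE
  for (g in seq_len(arch$p)) {
    mem <- which(isE & instc$cluster_of == g)
    sub <- W[mem, mem]
    expect_true(all(sub[sub != 0] == arch$Jplus["E", "E"]))
  }
  # Jplus = J gives the uniform weight multiset
  arch0 <- tiny_arch(Jplus_ratio = 1)
  inst0 <- build_clustered(arch0, neuron, seed = 3)
  expect_setequal(unique(inst0$syn$w), unique(as.numeric(arch0$J)))
})

test_that("arousal modulations set background rates as specified", {
  arch <- tiny_arch()
  neuron <- neuron_params()
  inst <- build_clustered(arch, neuron, seed = 1)
  base <- assign_external_rates(inst, arousal_modulation("mean"))
  expect_true(all(base[inst$pop == "E"] == arch$nu_o_E))
  expect_true(all(base[inst$pop == "I"] == arch$nu_o_I))
  # mean modulation scales uniformly
  up <- assign_external_rates(inst, arousal_modulation("mean", dM_E = 0.3))
  expect_equal(up[inst$pop == "E"], base[inst$pop == "E"] * 1.3)
  expect_equal(up[inst$pop == "I"], base[inst$pop == "I"])
  # heterogeneity: variance (dH nu_o)^2 before clipping, never negative
  bigarch <- arch_params(N_E = 4000, N_I = 400, p = 1, f_E = 1e-3,
                         f_I = 1e-3, p_EE = 0.01, p_EI = 0.1, p_IE = 0.01,
                         p_II = 0.1, J_EE = 0.02, J_EI = -0.08,
                         J_IE = 0.02, J_II = -0.1, C_ext_E = 30,
                         C_ext_I = 30, J_ext_E = 0.02, J_ext_I = 0.02,
                         nu_o_E = 15, nu_o_I = 10)
  binst <- build_uniform(bigarch, neuron, seed = 2)
  z <- arousal_z(binst, seed = 5)
  dh <- 0.2
  het <- assign_external_rates(binst,
                               arousal_modulation("heterogeneity",
                                                  dH_E = dh), z)
  hetE <- het[binst$pop == "E"]
  target_var <- (dh * bigarch$nu_o_E)^2
  expect_lt(abs(var(hetE) - target_var) / target_var, 0.1)
  het2 <- assign_external_rates(binst,
                                arousal_modulation("heterogeneity",
                                                   dH_E = 3), z)
  expect_gte(min(het2), 0)
  expect_true(any(het2[binst$pop == "E"] == 0))
  expect_error(arousal_modulation("heterogeneity", dH_E = -0.1))
})

test_that("clusters share one quenched realization of the input distribution", {
  arch <- tiny_arch()
  inst <- build_clustered(arch, neuron_params(), seed = 1)
  z <- arousal_z(inst, seed = 9)
  zs <- lapply(seq_len(arch$p), function(g)
    sort(z[inst$pop == "E" & inst$cluster_of == g]))
  for (g in 2:arch$p) expect_equal(zs[[g]], zs[[1]])
})

test_that("stimulus sets target the configured fractions and match counts", {
  arch <- tiny_arch()
  neuron <- neuron_params()
  inst <- build_clustered(arch, neuron, seed = 2)
  stims <- make_stimulus_set(inst, n_stimuli = 5, seed = 4)
  expect_length(stims, 5)
  g_E <- round(arch$f_E * arch$N_E)
  for (s in stims) {
    expect_length(s$targeted_clusters, round(0.5 * arch$p))
    expect_length(s$targeted_cells,
                  round(0.5 * arch$p) * round(0.5 * g_E))
    expect_true(all(inst$pop[s$targeted_cells] == "E"))
  }
  # saturation: all clustered E cells targeted
  full <- make_stimulus_set(inst, n_stimuli = 1, frac_clusters = 1,
                            frac_cells = 1, seed = 4)
  expect_setequal(full[[1]]$targeted_cells,
                  which(inst$pop == "E" & inst$cluster_of <= arch$p))
  # uniform instance gets a matched total count
  instu <- build_uniform(arch, neuron, seed = 2)
  stimu <- make_stimulus_set(instu, n_stimuli = 2, seed = 4)
  expect_length(stimu[[1]]$targeted_cells, length(stims[[1]]$targeted_cells))
  expect_error(make_stimulus_set(inst, frac_clusters = 0), "fractions")
})

test_that("stimulus waveform is causal, peak-normalized and E-specific", {
  spec <- structure(list(stim_id = 1, targeted_clusters = 1,
                         targeted_cells = 1:5, A_stim_E = 0.2,
                         tau_r = 0.02, tau_d = 0.1, t_stim = 1),
                    class = "stimulus_spec")
  expect_equal(stimulus_current(0.5, spec, 10, 100, 0.02), 0)
  expect_equal(stimulus_current(1, spec, 10, 100, 0.02), 0)
  tgrid <- seq(1, 2, by = 1e-5)
  s <- stimulus_current(tgrid, spec, 10, 100, 0.02)
  expect_lt(abs(max(s) / (0.2 * 10 * 100 * 0.02) - 1), 1e-6)
  bad <- spec; bad$tau_d <- 0.01
  expect_error(stimulus_current(1.5, bad, 10, 100, 0.02), "tau_d")
})
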