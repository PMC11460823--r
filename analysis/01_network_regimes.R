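#!/usr/bin/env Rscript
# Baseline regimes of the two architectures.
#
# The uniform network settles into irregular, stationary asynchronous
# firing near its mean-field rates; the clustered network with potentiated
# within-cluster coupling develops metastable cluster states. The
# mean-field scan over the intracluster coupling locates where cluster
# states appear, and the simulated active-cluster rate is matched to its
# mean-field counterpart.

library(arousalnet)
dir.create("results", showWarnings = FALSE)

cfg <- default_config("reduced")
neuron <- cfg$neuron

## uniform baseline: simulated vs mean-field rates
arch_u <- cfg$arch; arch_u$Jplus <- arch_u$J
inst_u <- build_uniform(arch_u, neuron, seed = 1)
nu0 <- assign_external_rates(inst_u, arousal_modulation("mean"))
sp <- simulate_trial(inst_u, nu0, NULL,
                     sim_config(trial_duration = 5, t_stim = 4.9), seed = 1)
rE <- nrow(sp[sp$unit <= inst_u$n_E]) / inst_u$n_E / 5
rI <- nrow(sp[sp$unit > inst_u$n_E]) / (inst_u$n - inst_u$n_E) / 5
mft_u <- solve_mft(arch_u, neuron, nA = 0)
cat(sprintf("uniform network: simulated E/I rates %.2f/%.2f spk/s, mean-field %.2f/%.2f\n",
            rE, rI, mft_u$rates[1], mft_u$rates[cfg$arch$p + 2]))

## mean-field scan of the intracluster coupling
grid <- cfg$arch$J["E", "E"] * seq(6, 12, by = 0.25)
rows <- lapply(grid, function(jp) {
  a <- cfg$arch; a$Jplus["E", "E"] <- jp
  s1 <- solve_mft(a, neuron, nA = 1, nu_high = 40)
  s2 <- solve_mft(a, neuron, nA = 2, nu_high = 40)
  data.frame(Jplus_EE = jp,
             nA1 = s1$state_kind, nA1_up = if (s1$state_kind ==
               "cluster_state") s1$nu_up else NA,
             nA2 = s2$state_kind, nA2_up = if (s2$state_kind ==
               "cluster_state") s2$nu_up else NA)
})
scan <- do.call(rbind, rows)
write.csv(scan, "results/coupling_scan.csv", row.names = FALSE)
onset <- scan$Jplus_EE[which(scan$nA1 == "cluster_state")[1]]
cat(sprintf("mean-field cluster states appear at Jplus_EE >= %.4f (ratio %.2f)\n",
            onset, onset / cfg$arch$J["E", "E"]))

## simulated metastability at the shipped coupling + coupling matching
inst_c <- build_clustered(cfg$arch, neuron, seed = 1)
nu0c <- assign_external_rates(inst_c, arousal_modulation("mean"))
traces <- lapply(1:5, function(k) {
  spc <- simulate_trial(inst_c, nu0c, NULL,
                        sim_config(trial_duration = 2, t_stim = 1.9),
                        seed = 10 + k)
  cluster_rates(spc[spc$unit <= inst_c$n_E],
                inst_c$cluster_of[seq_len(inst_c$n_E)], t_range = c(0, 2))
})
act <- activation_summary(traces, window = c(0.2, 1.9))
cat(sprintf("clustered simulation: most likely nA = %d, active %.1f / inactive %.1f spk/s\n",
            act$nA_star, act$rate_up[as.character(act$nA_star)],
            act$rate_down[as.character(act$nA_star)]))
m <- match_intracluster_coupling(act$rate_up[as.character(act$nA_star)],
                                 cfg$arch, neuron,
                                 coupling_grid = grid,
                                 nA_star = max(act$nA_star, 1))
cat(sprintf("matched mean-field coupling: %.4f (simulation uses %.4f)\n",
            m$Jplus_mft, cfg$arch$Jplus["E", "E"]))
write.csv(m$grid, "results/coupling_match.csv", row.names = FALSE)
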