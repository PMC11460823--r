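# arousalnet

Cortical sensory coding is often best at moderate arousal: decoding of tone
identity from auditory-cortex populations follows an inverted-U as a
function of pupil-indexed arousal. `arousalnet` implements a circuit-level
account of that observation and everything needed to probe it: clustered
excitatory/inhibitory spiking networks whose metastable cluster dynamics
are controlled by an arousal-like modulation of background input, the
mean-field theory of the underlying attractor transition, the full spike
analysis battery (population decoding, single-cell discriminability,
cluster activation statistics, multitaper spectra, Fano factors), and a
synthetic extracellular-session generator with the matching data-side
pipeline (pupil preprocessing, unit quality control, tone-responsiveness,
pupil-binned analyses).

## The model

Networks of leaky integrate-and-fire neurons with exponential synapses:

    tau_m dV_i/dt = -V_i + tau_m (I_rec,i + I_bg,i + I_stim,i)

with threshold/reset spiking and refractoriness. In the clustered
architecture the E and I populations are arranged into `p` assemblies;
within-cluster weights are potentiated (`J+`) and between-cluster weights
depressed to the value `J-` that preserves the summed synaptic weight of
the matched uniform network. Background input is an aggregate Poisson
process per cell. Arousal enters as a modulation of the background rates:

* input-mean modulation: `nu_i = nu_o (1 + dM)`,
* input-heterogeneity modulation: `nu_i = nu_o (1 + z_i dH)`, with
  `z_i ~ N(0,1)` quenched per realization and clipped at zero.

With strong intracluster coupling the network is metastable: subsets of
clusters activate at high rate and switch stochastically. Increasing `dH`
dissolves this multi-attractor regime into a single attractor; stimulus
coding is best near the transition. The mean-field module solves the
self-consistent population rates (plain and with quenched disorder) through
the LIF transfer function

    Phi = [tau_ref + tau_m sqrt(pi) * int_{q_r}^{q_t} erfcx(-x) dx]^-1

with synaptic-filtering boundary corrections, and a two-cluster effective
theory turns the attractor structure into a one-dimensional potential whose
barrier height shrinks with `dH` until the wells merge.

## Worked example

```r
library(arousalnet)

cfg  <- default_config("reduced")          # 800 neurons, 12 clusters
inst <- build_clustered(cfg$arch, cfg$neuron, seed = 1)
z    <- arousal_z(inst, seed = 2)
stim <- make_stimulus_set(inst, t_stim = 1, seed = 3)

nu  <- assign_external_rates(inst,
         arousal_modulation("heterogeneity", dH_E = 0.1), z)
ts  <- run_experiment(inst, nu, stim,
         sim_config(trial_duration = 1.8, t_stim = 1,
                    n_trials_per_stimulus = 15, seed = 4))
dec <- model_feature_sample(ts, n_runs = 5, seed = 5)
dec$peak_accuracy
```

A full sweep over `dH_E in {0, 0.1, 0.2, 0.3, 0.4}` (three network
realizations, `arousal_sweep(seed = 1)`) produces, after averaging over
realizations:

| dH_E | accuracy | rate gap (spk/s) | timescale (s) | FF_spont |
|------|----------|------------------|---------------|----------|
| 0.0  | 0.27     | 52.6             | 0.56          | 4.43     |
| 0.1  | 0.31     | 49.3             | 0.49          | 3.67     |
| 0.2  | 0.36     | 32.1             | 0.16          | 1.53     |
| 0.3  | 0.39     | 13.4             | 0.05          | 0.65     |
| 0.4  | 0.37     | 8.5              | 0.04          | 0.54     |

Decoding accuracy peaks at an interior modulation strength, while the
active/inactive cluster-rate gap, the cluster activation timescale, the
low-frequency spontaneous power and the spontaneous/evoked Fano factors
all fall as the modulation dissolves the metastable regime. The matched
uniform network decodes
strictly worse at `dH_E = 0.4` than at 0. The effective two-cluster
potential barrier decreases from ~129 to ~7.5 over `dH_E in [0, 0.4]` and
the double well merges into a single well by `dH_E = 0.5`
(`barrier_height_sweep(default_config("two_cluster")$arch, ...)`).

The numbered scripts under `analysis/` run these studies end to end and
write tidy tables under `results/`.

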