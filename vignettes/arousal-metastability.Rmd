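---
title: "Metastable cluster dynamics, arousal modulations, and stimulus coding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metastable cluster dynamics, arousal modulations, and stimulus coding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(arousalnet)
```

# The model

`arousalnet` simulates recurrent networks of leaky integrate-and-fire
neurons with exponential synaptic currents. The membrane potential of cell
`i` in population `a` (E or I) obeys

$$\tau_m^a \dot V_i = -V_i + \tau_m^a\,(I^{rec}_i + I^{bg}_i + I^{stim}_i),$$

with spikes at threshold `V_th`, reset to `V_r`, and an absolute refractory
period. Recurrent excitatory and inhibitory currents are low-pass filters
of presynaptic spikes with time constants `tau_syn_E`, `tau_syn_I`; a
presynaptic spike through a synapse of weight `J` adds `J / tau_syn` to the
corresponding current, so its voltage-integral contribution is `J`.
Background input to every cell is an aggregate Poisson process of rate
`C_ext * nu_ext` through synapses of weight `J_ext`; by superposition this
is statistically identical to `C_ext` independent external synapses, which
is how the model is specified. Sensory stimuli are deterministic currents
`A * nu_o * C_ext * J_ext * s(t)` applied to targeted excitatory cells,
with `s(t)` a peak-normalized difference of exponentials.

Two architectures share every cellular parameter. In the *uniform* network,
each cell of type `a` receives exactly `C_ab = p_ab N_b` synapses of weight
`J_ab` from randomly chosen cells of type `b`. In the *clustered* network
both populations split into `p` assemblies plus an unclustered background;
within-cluster weights are potentiated to `J+` while between-cluster and
cluster-background weights are depressed to

$$J^-_{ab} = \frac{(f_a + f_b - p f_a f_b)\,J_{ab} - f_a f_b\,J^+_{ab}}
                  {f_a + f_b - p f_a f_b - f_a f_b},$$

which keeps the total summed synaptic weight of the two architectures
identical. Per-cell in-degrees are kept exact: the per-class counts
(`f_b C_ab` same-cluster, `(p-1) f_b C_ab` other clusters,
`(1 - p f_b) C_ab` background) are rounded with the residual absorbed into
the other-cluster class, so every cell has exactly `C_ab` inputs of type
`b` and the clustered and uniform networks have identical synapse counts.
The summed-weight identity is exact to machine precision whenever cluster
sizes and class counts are integers (the conservation checks sample such
architectures); with rounding it holds to a relative error of order
`1/(f_b C_ab)`.

## Arousal as a background-input modulation

Arousal is modeled as a static change of the background rates. The *mean*
modulation scales every cell of a population: `nu_i = nu_o (1 + dM)`. The
*heterogeneity* modulation draws a quenched standard-normal `z_i` per cell
and sets `nu_i = nu_o (1 + z_i dH)`, truncated at zero (truncation, not
redraw), which raises the spatial variance `(dH nu_o)^2` while leaving the
mean approximately unchanged. In the clustered network each assembly reuses
the same realization of the within-cluster draw (cells at the same
within-cluster slot share `z`), so all clusters receive the same
spatially-averaged input; background cells draw independently. The
`z`-vector is drawn once per network realization and reused across all
modulation strengths, making the sweep a quenched family.

## Integration scheme

The subthreshold dynamics are linear, so each time step advances the state
by exact exponential propagators (membrane and synaptic decay factors plus
the cross-term coefficient), with the stimulus treated as constant within a
step. Spikes are detected at grid points, forced to the grid, and delivered
at the start of the next step; refractory cells stay clamped at reset.
Background arrivals are generated by exponential gap sampling from R's RNG,
so identical seeds give bit-identical spike output. The default step is
`dt = 0.5e-4` s; halving it changes population rates by well under 2%.
Multiple threshold crossings within one step are excluded by the refractory
clamp; simultaneous spikes are processed in cell-index order.

# Mean-field theory

The `2(p+1)` populations (p E clusters, E background, p I clusters, I
background) are described under the diffusion approximation: the input to
population `(a, g)` is Gaussian with mean `mu` and variance `sigma^2`
assembled from same-cluster (`J+`), other-cluster and background (`J-`),
background-to-background (`J`) and external terms. Self-consistent rates
solve `nu = Phi(mu(nu), sigma(nu))` with the LIF transfer function

$$\Phi = \Big[\tau_{ref} + \tau_m \sqrt{\pi}
         \int_{q_r}^{q_t} e^{x^2}\,\mathrm{erfc}(-x)\,dx\Big]^{-1},$$

where the integration bounds include the synaptic-filtering boundary shift
`a sqrt(tau_s / tau_m)` with `a = -zeta(1/2)/2 = 0.730177254404794`.

Numerics: the integrand is evaluated through the identity
`e^{x^2} erfc(-x) = erfcx(-x)`, and the integral decomposes exactly into
`2 int_0^q e^{x^2} dx - int_0^{|q|} erfcx(u) du`; both pieces are tabulated
once on fine grids (the first in log space) and splined, giving
machine-precision agreement with adaptive quadrature and microsecond-scale
evaluation. Solutions use damped fixed-point iteration with step-size
recovery (tolerance `1e-10` on rates, residual reported); multistability is
mapped by seeding the first `nA` cluster rates at `nu_high = 50` spikes/s
and the rest at `nu_low = 2` (the seed values are solver bias only). A
solution is reported as a cluster state only when the number of active
clusters at convergence matches the seed.

Under the heterogeneity modulation the rates within each population are
parameterized by the quenched variable `z`:
`nu(z) = Phi(mu_bar + Delta z, sigma)`, with `Delta^2` collecting the
external quenched variance `(C_ext J_ext dH nu_o)^2` plus the recurrent
feedback of the rate variances `s^2`; the spatial heterogeneity of `sigma`
is neglected. Population means and variances are Gauss-Hermite integrals
(60 nodes by default). At 40 versus 80 nodes the rate integral agrees to
about `1e-6` relative — the integrand inherits the transfer function's
threshold structure, so convergence is rapid but not to the `1e-12` one
would see for an analytic integrand. At `dH = 0` the quenched theory
reduces exactly to the plain one.

## Quantitative reach of the mean-field description

With the shipped synaptic time constant (`tau_syn = 5` ms, `tau_m = 20`
ms), the first-order boundary-shift correction leaves a systematic 10-20%
overestimate of simulated rates; the theory is therefore used
qualitatively, and the `match_intracluster_coupling()` procedure aligns the
mean-field intracluster coupling to the simulated active-cluster rate
before comparing trends — simulations develop cluster states at weaker
coupling than the theory predicts, as expected for finite networks with
non-negligible synaptic filtering. The transfer-function implementation
itself is validated against long single-neuron simulations in the regime
where its assumptions hold (fast synapses, `tau_s = 0.5` ms, and synaptic
kicks below ~5% of threshold, enforced by choosing `(mu, sigma)` with
`J = sigma^2 / mu` small); there it tracks 120-second simulations to within
10% over a 5x5 grid.

## Effective two-cluster theory

To describe transitions rather than just fixed points, a reduced network
(two E clusters, E background, one I pool, inter-cluster weights not
depressed) is analyzed by freezing the two cluster rates, solving the
ambient populations self-consistently (short damped phase plus Newton
iterations on the ambient residual), and computing the induced cluster
rates. The flow `F(nu) = nu_out - nu_in` on the `(nu1, nu2)` plane has two
stable asymmetric fixed points (the cluster states) joined by an unstable
symmetric point. Integrating `-F . dl` along the piecewise-linear path
well-saddle-well yields a one-dimensional potential; the straight-segment
path is a convention, so the barrier height `h` is meaningful in its trend
across `dH`, not in absolute units. Under `dH > 0` the rate-variance
feedback is dropped (`s^2 = 0`), keeping each population summarized by its
mean rate. With the shipped two-cluster configuration, `h` falls
monotonically from about 129 at `dH = 0` to about 7.5 at `dH = 0.4` and
the wells merge (single fixed point, `h = 0`) by `dH = 0.5`.

# Parameters

No quantitative parameter table accompanies the protocol this package
models, so all concrete values are package calibrations, recorded in the
bundled YAML configs with provenance notes. Shared cell parameters:
`tau_m = 20` ms, thresholds 1.5 (E) and 0.75 (I), reset 0, refractory 5 ms,
`tau_syn = 5` ms. Protocol-level values are fixed by the study design:
`dt = 0.5e-4` s, five stimuli targeting half the clusters and half of each
targeted cluster's E cells, stimulus onset at 1 s, the activation threshold
15 spikes/s, the 25 ms rate kernel, the `[-0.8, -0.1]` s pre-onset analysis
window, 100 ms count windows (20 ms steps in the model), time-bandwidth 5
with 9 tapers, and the `dH` range `[0, 0.4]`.

* `reduced` (the workhorse): 640 E / 160 I cells, `p = 12` clusters,
  `f = 0.075`, `p_EE = 0.35`, other connection probabilities 0.5,
  `J_EE = 0.018`, `J_EI = -0.1`, `J_IE = 0.025`, `J_II = -0.125`, external
  in-degree 128 with `J_ext = (0.06, 0.08)` and baseline rates calibrated
  through the uniform-network mean-field equations to target (3, 8)
  spikes/s. Within-cluster potentiation 8.25 (E-to-E) and 1.75 (inhibitory
  pathways) places the unmodulated network in the metastable regime with
  activation periods of a few hundred milliseconds that shorten and vanish
  across `dH in [0, 0.4]`. The external weight/rate split was chosen with
  the event rate of the background process in mind (about 1600 aggregate
  events per second per cell).
* `full`: 1600 E / 400 I, `p = 18` (one decoding feature per cluster plus
  background = 19), `f = 0.05`, E-to-E potentiation ratio 15.75. Used for
  mean-field analyses; its multistability (coexisting solutions with
  several active clusters) is part of the test suite.
* `two_cluster`: 800 E / 200 I, two clusters of 30% of the E population,
  potentiation ratio 5, no inter-cluster depression.
* Stimulus amplitude `A = 0.075` (7.5% of the baseline background mean).
  This near-threshold value is deliberate: the stimulus then carries little
  directly-decodable signal and coding relies on cluster amplification,
  which is the regime in which the inverted-U emerges. With much stronger
  stimuli, accuracy instead grows monotonically with `dH` because direct
  single-cell responses dominate once the attractors dissolve.

# The analysis battery

* **Decoding** uses a multiclass linear discriminant with shared
  within-class covariance; a small spectral ridge (`1e-4` of the mean
  diagonal) keeps rank-deficient windows solvable, and the decision rule is
  cross-checked against an independent LDA implementation in the tests.
  Repeated stratified 5-fold cross-validation (10 repeats) on sliding
  100 ms windows; the peak of the accuracy timecourse (earliest window on
  ties) summarizes performance. Model decoding samples one E cell per
  cluster plus one background cell and averages runs. Shuffle nulls permute
  labels with one stratified 80/20 split each.
* **Discriminability**: pairwise d-prime with pooled SD
  `sqrt((s_a^2 + s_b^2)/2)`; pairs with zero pooled SD are dropped. The
  per-cell pair average uses |d'| since pair orientation is arbitrary; the
  shuffled-label floor of the summary is then the positive small-sample
  bias of the magnitude, and informative data sit far above it.
* **Cluster metrics**: rates from 25 ms Gaussian-kernel smoothing at 1 ms
  steps, activation at `>= 15` spikes/s, `P(nA)` and conditioned
  active/inactive rates pooled over pre-onset time points, activation
  durations averaged within then across trials. Window-clipped activation
  periods enter at their truncated duration (a bias of order
  window/timescale that saturates the estimate when switching is slower
  than the 0.7 s window). For sweep summaries a condition with no
  activation periods contributes a timescale of zero (the op itself flags
  it as undefined). The evoked metrics (cluster signal, reliability with
  the 25 ms persistence rule on baseline-subtracted rates, targeted
  activation fractions) are computed over the peak decoding window of the
  same trial set.
* **Spectra**: multitaper estimates of 1 ms-binned spike trains, mean
  removed (the rate line at zero frequency), `2TW - 1 = 9` Slepian tapers
  with unit weights, normalized per trial by the mean bin count so a
  Poisson train has unit spectrum. Tapers come from a Lanczos
  diagonalization of the standard tridiagonal commuting matrix, cached per
  length. Low-frequency power averages the 1-4 Hz grid points (endpoints
  inclusive).
* **Fano factors**: variance/mean of windowed counts across trials;
  spontaneous from the window ending at onset, evoked at the minimum of the
  population-averaged timecourse within 200 ms after onset; cells below 1
  spike/s excluded.

# The synthetic-session generator

The generator emulates the statistical structure the data-side analyses
consume, not the biophysics of a recording: alternating spontaneous and
stimulation blocks; five tones (25 ms, 775 ms inter-stimulus interval)
drawn uniformly; a latent pupil process (logistic-squashed
Ornstein-Uhlenbeck, 20 s timescale) sampled at 1 ms and expressed as
percent of maximum; treadmill speed at 100 Hz with occasional bouts;
inhomogeneous-Poisson spiking whose rate is
`base * gain(pupil percentile) * slow_noise * (1 + evoked kernel)`.
Per-unit gain curves (monotone up/down, inverted-U, flat) act on the
session-relative pupil percentile so the configured shapes span the
observed arousal range symmetrically, and can be wired to the spontaneous
rate, the evoked component, or both. The slow multiplicative rate noise has
a 5 s timescale — short enough that decile averages decorrelate from the
pupil and the flat configuration is a valid null (about 5% classification
false positives at alpha = 0.05). Template amplitudes per spike support
injected defects: a second amplitude mode in part of the session, and drift
into a detection floor (amplitudes clipped at 10% of the unit's mean,
emulating thresholded spike detection). Pupil artifacts are injected step
jumps.

What passing the recovery tests shows — and does not show: the pipeline
correctly distinguishes inverted-U, monotone and flat pupil-gain ground
truths and its null calibrations hold under this generator's assumptions
(Poisson spiking, smooth gain curves, stationary tuning). Real recordings
add spike-sorting errors, non-Poisson firing, drifting tuning and
correlated noise that the generator deliberately omits; the QC defects
model only the amplitude signatures the selection procedure screens for.

Data-side conventions follow the experimental protocol: pupil jump
artifacts (normalized consecutive-sample difference above 0.08) mask
`[-250, +500]` ms around the jump, traces are smoothed with a 1/30 s moving
average and renormalized; the amplitude QC uses non-overlapping 5-minute
windows, Gaussian-kernel densities with Scott's-rule bandwidth, a peak
height ratio of at most 10 with at least 40 percent peak-location
separation for multimodality (rejection at 10% of windows), a 15 percent
floor proximity and 25 percent peak-location range for drift, and a 0.25
spikes/s rate floor; percent differences use the symmetric convention
`200 |a - b| / (a + b)`. The jump check compares consecutive 1 ms samples
(the stated half-millisecond interval is below the native camera frame
spacing, so the 1 ms grid difference is the faithful discrete analogue).
Tone-responsiveness compares 100 ms windows slid at 1 ms through the 200 ms
evoked period against pooled baseline windows with Mann-Whitney tests,
Bonferroni correction, and a 5 ms minimum run of significance.

# Problem sizes

The standard sweep uses the reduced architecture with five modulation
strengths, 15 trials per stimulus, three network realizations, 1.8 s evoked
trials (onset at 1 s, preserving the 0.8 s pre-onset window and 0.6 s
post-onset span), ten 2.5 s spontaneous trials per condition for spectra,
five decoding cell-subsamples, and 64 spectral cells; these are the
package's chosen study sizes and are what the tests and the acceptance
script run. The full-size configuration is exercised at the mean-field
level.

# Known limitations

* The mean-field theory is quantitative only at small `tau_s / tau_m`; at
  the shipped value it requires the coupling-matching step for
  simulation comparisons.
* In the reduced network the low-frequency spontaneous power is not
  strictly monotone in `dH`: at `dH = 0` switching is slow enough that part
  of the attractor dynamics falls below the 1-4 Hz band, so the power peaks
  at a small positive `dH` before collapsing. The rank correlation across
  the grid is still clearly negative.
* Activation timescales are right-censored by the 0.7 s analysis window.
* The barrier height depends on the straight-segment path convention; only
  its trend across `dH` is interpreted.
* No synaptic delays, conductance-based synapses, plasticity, or
  tonotopic structure.
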