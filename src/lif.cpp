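// Leaky integrate-and-fire network with exponential synapses.
//
// Linear subthreshold dynamics are advanced with their exact exponential
// propagators over each time step; spikes are detected at grid points,
// forced to the grid, and delivered at the start of the next step.
// Background input is an aggregate Poisson process per cell (rate
// C_ext * nu_ext), realized by exponential gap sampling from R's RNG so
// that runs are reproducible under set.seed().

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
List lif_run(int n_E, int n_I,
             IntegerVector syn_ptr,    // length n+1, 0-based CSR by presyn
             IntegerVector syn_post,   // 0-based postsynaptic ids
             NumericVector syn_w,      // signed weights
             NumericVector bg_rate,    // per-cell aggregate Poisson rate (Hz)
             NumericVector bg_w,       // per-cell external synaptic weight
             NumericVector stim_amp,   // per-cell stimulus amplitude (0 = none)
             double t_stim, double tau_r, double tau_d, double s_gamma,
             double duration, double dt,
             double tau_m_E, double tau_m_I,
             double V_th_E, double V_th_I,
             double V_r_E, double V_r_I,
             double tau_ref_E, double tau_ref_I,
             double tau_syn_E, double tau_syn_I,
             bool record_voltage = false, int voltage_cell = 0) {
  const int n = n_E + n_I;
  const int n_steps = (int) std::round(duration / dt);

  // per-population propagator coefficients
  const double tm[2]   = {tau_m_E, tau_m_I};
  const double vth[2]  = {V_th_E, V_th_I};
  const double vr[2]   = {V_r_E, V_r_I};
  const int    nref[2] = {(int) std::round(tau_ref_E / dt),
                          (int) std::round(tau_ref_I / dt)};
  double dm[2], cE[2], cI[2], cS[2];
  const double dsE = std::exp(-dt / tau_syn_E);
  const double dsI = std::exp(-dt / tau_syn_I);
  for (int a = 0; a < 2; ++a) {
    dm[a] = std::exp(-dt / tm[a]);
    cE[a] = (dm[a] - dsE) / (1.0 / tau_syn_E - 1.0 / tm[a]);
    cI[a] = (dm[a] - dsI) / (1.0 / tau_syn_I - 1.0 / tm[a]);
    cS[a] = tm[a] * (1.0 - dm[a]);
  }

  std::vector<double> V(n), IE(n, 0.0), II(n, 0.0);
  std::vector<int> refc(n, 0);
  std::vector<double> next_bg(n);
  const double *p_rate = bg_rate.begin();
  const double *p_bgw = bg_w.begin();
  const double *p_samp = stim_amp.begin();
  const int *p_ptr = syn_ptr.begin();
  const int *p_post = syn_post.begin();
  const double *p_w = syn_w.begin();

  // initial conditions: V ~ U[V_r, V_th); then background gap schedule
  for (int i = 0; i < n; ++i) {
    const int a = (i < n_E) ? 0 : 1;
    V[i] = vr[a] + (vth[a] - vr[a]) * unif_rand();
  }
  for (int i = 0; i < n; ++i)
    next_bg[i] = (p_rate[i] > 0) ? exp_rand() / p_rate[i] : R_PosInf;

  std::vector<int> spike_id;
  std::vector<double> spike_t;
  std::vector<int> fired;
  fired.reserve(64);
  NumericVector vtrace(record_voltage ? n_steps : 0);

  const double inv_tsE = 1.0 / tau_syn_E, inv_tsI = 1.0 / tau_syn_I;
  bool any_stim = false;
  for (int i = 0; i < n; ++i) if (p_samp[i] != 0.0) { any_stim = true; break; }

  for (int k = 0; k < n_steps; ++k) {
    const double t1 = (k + 1) * dt;
    // stimulus waveform at the step start
    double s_t = 0.0;
    if (any_stim) {
      const double t0 = k * dt;
      if (t0 >= t_stim) {
        const double u = t0 - t_stim;
        s_t = s_gamma * (std::exp(-u / tau_d) - std::exp(-u / tau_r));
      }
    }
    fired.clear();
    // one pass per population so the coefficients are loop constants
    for (int a = 0; a < 2; ++a) {
      const int lo = (a == 0) ? 0 : n_E, hi = (a == 0) ? n_E : n;
      const double dm_a = dm[a], cE_a = cE[a], cI_a = cI[a], cS_a = cS[a];
      const double vth_a = vth[a], vr_a = vr[a];
      const int nref_a = nref[a];
      for (int i = lo; i < hi; ++i) {
        // background arrivals in [t0, t1), forced to the grid
        if (next_bg[i] < t1) {
          int cnt = 0;
          const double inv_r = 1.0 / p_rate[i];
          do { ++cnt; next_bg[i] += exp_rand() * inv_r; }
          while (next_bg[i] < t1);
          IE[i] += cnt * p_bgw[i] * inv_tsE;
        }
        const double newIE = IE[i] * dsE;
        const double newII = II[i] * dsI;
        if (refc[i] > 0) {
          --refc[i];
          V[i] = vr_a;
        } else {
          double v = V[i] * dm_a + IE[i] * cE_a + II[i] * cI_a;
          if (s_t != 0.0 && p_samp[i] != 0.0) v += p_samp[i] * s_t * cS_a;
          if (v >= vth_a) {
            if (!(v < 1e12))  // catches NaN and blow-up
              stop("non-finite membrane potential at t = %f (cell %d)",
                   t1, i + 1);
            fired.push_back(i);
            v = vr_a;
            refc[i] = nref_a;
          }
          V[i] = v;
        }
        IE[i] = newIE;
        II[i] = newII;
      }
    }
    // propagate recurrent spikes (delivered into the next step's currents)
    for (size_t s = 0; s < fired.size(); ++s) {
      const int j = fired[s];
      spike_id.push_back(j + 1);
      spike_t.push_back(t1);
      if (j < n_E) {
        for (int e = p_ptr[j]; e < p_ptr[j + 1]; ++e)
          IE[p_post[e]] += p_w[e] * inv_tsE;
      } else {
        for (int e = p_ptr[j]; e < p_ptr[j + 1]; ++e)
          II[p_post[e]] += p_w[e] * inv_tsI;
      }
    }
    if (record_voltage) vtrace[k] = V[voltage_cell];
  }

  return List::create(_["unit"] = wrap(spike_id),
                      _["time"] = wrap(spike_t),
                      _["voltage"] = vtrace);
}
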