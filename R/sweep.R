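# Arousal-modulation sweeps over clustered (and matched uniform) networks:
# the package's standard simulation experiment. For each heterogeneity
# strength and network realization this runs evoked trials (five stimuli)
# plus spontaneous-only trials, then computes the full analysis battery:
# peak decoding accuracy, single-cell discriminability, cluster activation
# statistics and timescale, evoked cluster signal/reliability, spontaneous
# low-frequency power, and spontaneous/evoked Fano factors.
#
# Problem sizes default to the reduced architecture and short trials
# (onset at 1 s, 0.8 s analysis window before onset, 0.6 s after) so that
# a full sweep is tractable on a single core.

#' Run the clustered-network arousal sweep
#'
#' @param dh_grid heterogeneity strengths.
#' @param n_realizations network realizations (fresh connectivity and
#'   quenched draws per realization).
#' @param n_trials trials per stimulus per realization.
#' @param n_spont spontaneous-only trials (for spectra), 2.5 s each.
#' @param config model configuration (default: the bundled reduced
#'   architecture).
#' @param trial_duration,t_stim trial timing (s).
#' @param n_feature_runs cell-subsample repeats for decoding.
#' @param n_spectrum_cells E cells used for the spectral estimate.
#' @param seed base seed.
#' @param verbose print progress lines.
#' @return data.frame with one row per (dH_E, realization):
#'   `peak_accuracy`, `Dsc_prime`, `gap` (active minus inactive cluster
#'   rate), `nA_star`, `timescale` (0 when no activation periods),
#'   `any_activation`, `Cs`, `Cr`, `P_L`, `FF_spont`, `FF_evoked`,
#'   `delta_FF`.
#' @export
arousal_sweep <- function(dh_grid = c(0, 0.1, 0.2, 0.3, 0.4),
                          n_realizations = 3, n_trials = 15, n_spont = 10,
                          config = default_config("reduced"),
                          trial_duration = 1.8, t_stim = 1,
                          n_feature_runs = 5, n_spectrum_cells = 64,
                          seed = 1, verbose = FALSE) {
  arch <- config$arch
  neuron <- config$neuron
  rows <- list()
  for (r in seq_len(n_realizations)) {
    inst <- build_clustered(arch, neuron, seed = seed + 1000L * r)
    z <- arousal_z(inst, seed = seed + 1000L * r + 1L)
    stimuli <- make_stimulus_set(inst, t_stim = t_stim,
                                 seed = seed + 1000L * r + 2L)
    for (di in seq_along(dh_grid)) {
      dh <- dh_grid[di]
      nu_ext <- assign_external_rates(
        inst, arousal_modulation("heterogeneity", dH_E = dh), z)
      cfg <- sim_config(trial_duration = trial_duration, t_stim = t_stim,
                        n_trials_per_stimulus = n_trials,
                        seed = seed + 97L * r + 11L * di)
      ts <- run_experiment(inst, nu_ext, stimuli, cfg,
                           n_spont = n_spont, spont_duration = 2.5)
      met <- sweep_metrics(ts, stimuli, n_feature_runs = n_feature_runs,
                           n_spectrum_cells = n_spectrum_cells,
                           seed = seed + 7L * di + r)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(dH_E = dh, realization = r), met)
      if (verbose)
        message(sprintf("dH=%.2f r=%d acc=%.3f gap=%.1f tau=%.3f PL=%.2f",
                        dh, r, met$peak_accuracy, met$gap, met$timescale,
                        met$P_L))
    }
  }
  do.call(rbind, rows)
}

#' Analysis battery for one simulated condition
#'
#' @param ts a `trial_set` with evoked and (optionally) spontaneous trials.
#' @param stimuli the stimulus set used.
#' @param n_feature_runs,n_spectrum_cells,seed see [arousal_sweep()].
#' @return one-row data.frame of summary metrics.
#' @export
sweep_metrics <- function(ts, stimuli, n_feature_runs = 5,
                          n_spectrum_cells = 64, seed = 1) {
  inst <- ts$instance
  p <- inst$arch$p
  t_stim <- ts$t_stim
  evoked_trials <- which(!is.na(ts$trial_stim))
  labels <- ts$trial_stim[evoked_trials]
  spE <- ts$spikes[!is.na(ts$spikes$stim) & ts$spikes$unit <= inst$n_E]
  # decoding (cluster-sampled features) and discriminability
  dec <- model_feature_sample(ts, n_runs = n_feature_runs, seed = seed)
  spE_rel <- data.table::copy(spE)[, time := time - t_stim]
  unitsE <- seq_len(inst$n_E)
  cts <- sliding_counts(spE_rel, trials = evoked_trials, units = unitsE)
  dp <- dprime_pipeline(cts, labels)
  # cluster-rate traces per trial (relative to onset)
  cl_assign <- ifelse(inst$pop == "E", inst$cluster_of, NA_integer_)
  spE_all <- ts$spikes[ts$spikes$unit <= inst$n_E]
  sp_by_trial <- split(spE_all, by = "trial", keep.by = TRUE)
  empty_dt <- spE_all[0]
  traces <- lapply(evoked_trials, function(tr) {
    d <- sp_by_trial[[as.character(tr)]]
    if (is.null(d)) d <- empty_dt
    cluster_rates(d, cl_assign[seq_len(inst$n_E)],
                  t_range = c(0, ts$trial_duration))
  })
  # shift trace time axes to be onset-relative
  for (i in seq_along(traces)) traces[[i]]$time <- traces[[i]]$time - t_stim
  tracesC <- lapply(traces, function(tr) {
    tr$rate <- tr$rate[tr$clusters <= p, , drop = FALSE]
    tr$clusters <- tr$clusters[tr$clusters <= p]
    tr
  })
  spont_win <- c(-0.8, -0.1)
  act <- activation_summary(tracesC, spont_win)
  tau <- activation_timescale(tracesC, spont_win)
  peak_win <- c(cts$starts[dec$peak_window],
                cts$starts[dec$peak_window] + cts$window)
  targ <- lapply(labels, function(s) stimuli[[s]]$targeted_clusters)
  evm <- evoked_cluster_metrics(tracesC, targ, peak_win)
  # conditioned-rate gap at the most likely nA (0 when nothing activates)
  gap <- if (act$nA_star >= 1 &&
             is.finite(act$rate_up[as.character(act$nA_star)]))
    act$rate_up[as.character(act$nA_star)] -
      act$rate_down[as.character(act$nA_star)]
  else act$mean_gap
  # spectra from spontaneous-only trials
  P_L <- NA_real_
  spont_trials <- which(is.na(ts$trial_stim))
  if (length(spont_trials)) {
    sp_spont <- ts$spikes[is.na(ts$spikes$stim) &
                            ts$spikes$unit <= inst$n_E]
    rate_tot <- tabulate(sp_spont$unit, nbins = inst$n_E)
    dur_tot <- length(spont_trials) * ts$spont_duration
    eligible <- which(rate_tot / dur_tot >= 1)
    set.seed(seed)
    cells <- if (length(eligible) > n_spectrum_cells)
      sort(.draw(eligible, n_spectrum_cells)) else eligible
    sp_by_ut <- split(sp_spont[sp_spont$unit %in% cells],
                      by = c("unit", "trial"))
    pls <- vapply(cells, function(u) {
      stl <- lapply(spont_trials, function(tr) {
        d <- sp_by_ut[[paste(u, tr, sep = ".")]]
        if (is.null(d)) numeric(0) else d$time
      })
      est <- tryCatch(
        multitaper_point_spectrum(stl, ts$spont_duration),
        error = function(e) NULL)
      if (is.null(est)) NA_real_ else low_freq_power(est)
    }, numeric(1))
    P_L <- mean(pls, na.rm = TRUE)
  }
  # Fano factors from evoked counts, stimulated-cluster cells only
  stim_cells <- sort(unique(unlist(lapply(stimuli, function(s)
    s$targeted_cells))))
  ctsF <- list(counts = cts$counts[stim_cells, , , drop = FALSE],
               centers = cts$centers, starts = cts$starts,
               window = cts$window, step = cts$step)
  # inclusion: spontaneous rate >= 1 spk/s (pre-onset window of evoked
  # trials)
  pre_spikes <- spE[spE$time >= t_stim - 0.8 & spE$time < t_stim]
  pre_tab <- tabulate(pre_spikes$unit, nbins = inst$n_E)
  pre_counts <- pre_tab[stim_cells]
  rate_pre <- pre_counts / (0.8 * length(evoked_trials))
  okF <- rate_pre >= 1
  ff <- if (any(okF)) {
    fano_timecourse(list(counts = ctsF$counts[okF, , , drop = FALSE],
                         centers = ctsF$centers, starts = ctsF$starts,
                         window = ctsF$window, step = ctsF$step))
  } else NULL
  data.frame(
    peak_accuracy = dec$peak_accuracy,
    Dsc_prime = dp$Dsc_prime,
    gap = unname(gap),
    nA_star = act$nA_star,
    timescale = if (is.na(tau$timescale)) 0 else tau$timescale,
    any_activation = tau$n_periods > 0,
    Cs = evm$Cs, Cr = evm$Cr,
    P_L = P_L,
    FF_spont = if (is.null(ff)) NA_real_ else ff$FF_spont_mean,
    FF_evoked = if (is.null(ff)) NA_real_ else ff$FF_evoked_mean,
    delta_FF = if (is.null(ff)) NA_real_ else ff$delta_FF_mean)
}

#' Decoding-only sweep for the matched uniform network
#'
#' @inheritParams arousal_sweep
#' @return data.frame with `dH_E`, `realization`, `peak_accuracy`.
#' @export
uniform_sweep <- function(dh_grid = c(0, 0.4), n_realizations = 4,
                          n_trials = 15,
                          config = default_config("reduced"),
                          trial_duration = 1.8, t_stim = 1,
                          n_feature_runs = 5, seed = 1) {
  arch <- config$arch
  # uniform counterpart: no weight potentiation
  arch$Jplus <- arch$J
  neuron <- config$neuron
  rows <- list()
  for (r in seq_len(n_realizations)) {
    inst <- build_uniform(arch, neuron, seed = seed + 2000L * r)
    z <- arousal_z(inst, seed = seed + 2000L * r + 1L)
    stimuli <- make_stimulus_set(inst, t_stim = t_stim,
                                 seed = seed + 2000L * r + 2L)
    for (di in seq_along(dh_grid)) {
      dh <- dh_grid[di]
      nu_ext <- assign_external_rates(
        inst, arousal_modulation("heterogeneity", dH_E = dh), z)
      cfg <- sim_config(trial_duration = trial_duration, t_stim = t_stim,
                        n_trials_per_stimulus = n_trials,
                        seed = seed + 41L * r + 13L * di)
      ts <- run_experiment(inst, nu_ext, stimuli, cfg)
      dec <- model_feature_sample(ts, n_runs = n_feature_runs,
                                  seed = seed + 5L * di + r)
      rows[[length(rows) + 1L]] <-
        data.frame(dH_E = dh, realization = r,
                   peak_accuracy = dec$peak_accuracy)
    }
  }
  do.call(rbind, rows)
}
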