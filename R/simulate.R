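# Simulation drivers around the compiled LIF core.

#' Simulation configuration
#'
#' @param dt integration step (s). The subthreshold dynamics are advanced by
#'   their exact exponential propagators between grid points; spikes are
#'   forced to the grid.
#' @param trial_duration trial length (s).
#' @param t_stim stimulus onset (s), must precede `trial_duration`.
#' @param n_trials_per_stimulus trials per stimulus in [run_experiment()].
#' @param record_voltage record the membrane potential of one cell.
#' @param seed base seed; per-trial seeds are derived deterministically.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dt = 0.5e-4, trial_duration = 3.5, t_stim = 1,
                       n_trials_per_stimulus = 30, record_voltage = FALSE,
                       seed = 1) {
  if (dt <= 0) stop("dt must be positive")
  if (t_stim >= trial_duration) stop("t_stim must precede trial end")
  structure(list(dt = dt, trial_duration = trial_duration, t_stim = t_stim,
                 n_trials_per_stimulus = n_trials_per_stimulus,
                 record_voltage = record_voltage, seed = seed),
            class = "sim_config")
}

#' Simulate one trial of network activity
#'
#' Integrates the coupled membrane/synaptic dynamics with threshold-reset
#' spiking, refractory clamping, aggregate Poisson background input at
#' per-cell rate `C_ext * nu_ext`, and (optionally) a stimulus input applied
#' to the targeted E cells. Initial voltages are drawn uniformly in
#' `[V_r, V_th)`. Reproducible for a fixed `(instance, nu_ext, seed)`.
#'
#' @param instance a `network_instance`.
#' @param nu_ext per-cell external rates from [assign_external_rates()].
#' @param stimulus a `stimulus_spec` or `NULL` for a spontaneous trial.
#' @param config a [sim_config()].
#' @param seed integer seed for this trial.
#' @return A `data.table` of spikes with columns `unit`, `time`; attribute
#'   `voltage` when recorded.
#' @export
simulate_trial <- function(instance, nu_ext, stimulus = NULL, config,
                           seed = 1) {
  a <- instance$arch
  np <- instance$neuron
  stim_amp <- numeric(instance$n)
  t_stim <- config$trial_duration + 1  # never reached
  tau_r <- 0.02; tau_d <- 0.1; s_gamma <- 1
  if (!is.null(stimulus)) {
    stim_amp[stimulus$targeted_cells] <-
      stimulus$A_stim_E * a$nu_o_E * a$C_ext_E * a$J_ext_E
    t_stim <- stimulus$t_stim
    tau_r <- stimulus$tau_r
    tau_d <- stimulus$tau_d
    s_gamma <- .stim_gamma(tau_r, tau_d)
  }
  bg_rate <- ifelse(instance$pop == "E", a$C_ext_E, a$C_ext_I) * nu_ext
  bg_w <- ifelse(instance$pop == "E", a$J_ext_E, a$J_ext_I)
  set.seed(seed)
  res <- lif_run(instance$n_E, instance$n_I,
                 instance$syn$ptr, instance$syn$post - 1L, instance$syn$w,
                 bg_rate, bg_w, stim_amp,
                 t_stim, tau_r, tau_d, s_gamma,
                 config$trial_duration, config$dt,
                 np$tau_m_E, np$tau_m_I, np$V_th_E, np$V_th_I,
                 np$V_r_E, np$V_r_I, np$tau_ref_E, np$tau_ref_I,
                 np$tau_syn_E, np$tau_syn_I,
                 config$record_voltage, 0L)
  out <- data.table::data.table(unit = res$unit, time = res$time)
  if (config$record_voltage) data.table::setattr(out, "voltage", res$voltage)
  out
}

#' Run an experiment: evoked (and optionally spontaneous) trials
#'
#' Simulates `n_trials_per_stimulus` trials for each stimulus (plus
#' `n_spont` purely spontaneous trials if requested), with per-trial random
#' initial conditions and independent background realizations derived
#' deterministically from the config seed.
#'
#' @param instance a `network_instance`.
#' @param nu_ext per-cell external rates.
#' @param stimuli list of `stimulus_spec` (may be empty).
#' @param config a [sim_config()].
#' @param n_spont number of spontaneous-only trials appended (stimulus `NA`).
#' @param spont_duration duration of spontaneous-only trials (s).
#' @return A `trial_set`: list with `spikes` (`data.table`: `unit`, `time`,
#'   `trial`, `stim`), `t_stim`, `trial_duration`, `spont_duration`,
#'   `n_trials`, and the instance.
#' @export
run_experiment <- function(instance, nu_ext, stimuli, config,
                           n_spont = 0, spont_duration = 2.5) {
  jobs <- list()
  for (s in seq_along(stimuli))
    for (k in seq_len(config$n_trials_per_stimulus))
      jobs[[length(jobs) + 1L]] <- list(stim = s, rep = k)
  for (k in seq_len(n_spont))
    jobs[[length(jobs) + 1L]] <- list(stim = NA_integer_, rep = k)
  tabs <- vector("list", length(jobs))
  for (j in seq_along(jobs)) {
    stim_id <- jobs[[j]]$stim
    cfg <- config
    if (is.na(stim_id)) cfg$trial_duration <- spont_duration
    sp <- simulate_trial(instance, nu_ext,
                         if (is.na(stim_id)) NULL else stimuli[[stim_id]],
                         cfg, seed = config$seed * 100003L + j)
    if (nrow(sp)) {
      sp[, `:=`(trial = j, stim = stim_id)]
      tabs[[j]] <- sp
    }
  }
  spikes <- data.table::rbindlist(tabs[!vapply(tabs, is.null, logical(1))])
  structure(list(spikes = spikes, t_stim = config$t_stim,
                 trial_duration = config$trial_duration,
                 spont_duration = spont_duration,
                 n_trials = length(jobs),
                 trial_stim = vapply(jobs, function(j)
                   as.integer(j$stim), integer(1)),
                 instance = instance),
            class = "trial_set")
}
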