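# Cluster-level dynamics: smoothed cluster rates, activation states,
# nA statistics, activation timescales, and evoked cluster signal /
# reliability measures.

#' Time-varying cluster firing rates
#'
#' Convolves each unit's spike train with a Gaussian kernel (width `sigma`,
#' evaluated on a regular grid) and averages over the member cells of each
#' cluster.
#'
#' @param spikes `data.table` with columns `unit`, `time` (one trial).
#' @param assignments integer vector mapping unit id to cluster (background
#'   clusters are permitted and simply averaged like any other).
#' @param sigma Gaussian kernel width (s).
#' @param dt_grid rate-grid step (s).
#' @param t_range numeric length-2: time span of the grid.
#' @param clusters which cluster indices to return (default: all present in
#'   `assignments` except none).
#' @return list with `rate` (clusters x time matrix, spikes/s), `time`
#'   (grid centers), `clusters`, and `n_members` per cluster. Empty clusters
#'   yield an `NA` row and a warning-level flag in `empty`.
#' @export
cluster_rates <- function(spikes, assignments, sigma = 0.025,
                          dt_grid = 0.001, t_range,
                          clusters = sort(unique(assignments))) {
  tg <- seq(t_range[1], t_range[2], by = dt_grid)
  nt <- length(tg)
  # discrete Gaussian kernel, normalized to unit mass on the grid
  half <- ceiling(4 * sigma / dt_grid)
  kern <- stats::dnorm(seq(-half, half) * dt_grid, sd = sigma)
  kern <- kern / sum(kern) / dt_grid
  out <- matrix(NA_real_, length(clusters), nt)
  nm <- integer(length(clusters))
  for (k in seq_along(clusters)) {
    mem <- which(assignments == clusters[k])
    nm[k] <- length(mem)
    if (length(mem) == 0L) next
    st <- spikes$time[spikes$unit %in% mem]
    st <- st[st >= t_range[1] - half * dt_grid &
             st <= t_range[2] + half * dt_grid]
    counts <- numeric(nt + 2L * half)
    idx <- round((st - t_range[1]) / dt_grid) + half + 1L
    idx <- idx[idx >= 1L & idx <= length(counts)]
    tb <- tabulate(idx, nbins = length(counts))
    sm <- stats::filter(tb, kern, sides = 2)
    out[k, ] <- as.numeric(sm[(half + 1L):(half + nt)]) / nm[k]
  }
  list(rate = out, time = tg, clusters = clusters, n_members = nm,
       empty = clusters[nm == 0L], sigma = sigma, dt = dt_grid)
}

#' Threshold cluster activation states
#'
#' A cluster is active at time t when its rate meets or exceeds `theta`
#' (the conventional threshold is 15 spikes/s).
#'
#' @param trace output of [cluster_rates()].
#' @param theta activation threshold (spikes/s).
#' @return list with `active` (logical clusters x time) and `nA(t)`
#'   (integer vector, column sums).
#' @export
activation_states <- function(trace, theta = 15) {
  if (theta < 0) stop("theta must be non-negative")
  act <- trace$rate >= theta
  act[is.na(act)] <- FALSE
  list(active = act, nA = colSums(act), time = trace$time)
}

#' Distribution of the number of active clusters and conditioned rates
#'
#' Pools time points in an analysis window across trials, computes the
#' probability `P(nA)` of finding `nA` clusters active, the average rates of
#' active and inactive clusters conditioned on `nA`, and the most likely
#' count `nA_star`. Conditioned rates with `P(nA) < p_min` are flagged as
#' low-confidence.
#'
#' @param traces list of [cluster_rates()] outputs (one per trial).
#' @param window numeric length-2, analysis window on the trace time axis
#'   (the convention for spontaneous epochs is `[-0.8, -0.1]` s relative to
#'   stimulus onset).
#' @param theta activation threshold (spikes/s).
#' @param p_min confidence floor on `P(nA)`.
#' @return list with `P` (named probability vector over `0..p`), `nA_star`,
#'   `rate_up`, `rate_down` (per-`nA` conditioned rates), `low_confidence`
#'   (logical per `nA`), and the pooled `mean_gap` = mean active minus mean
#'   inactive rate over all time points (0 when no cluster is ever active).
#' @export
activation_summary <- function(traces, window, theta = 15, p_min = 0.1) {
  p <- nrow(traces[[1]]$rate)
  counts <- integer(p + 1L)
  sum_up <- sum_dn <- n_up <- n_dn <- numeric(p + 1L)
  all_up <- all_dn <- 0; nobs_up <- nobs_dn <- 0
  for (tr in traces) {
    sel <- tr$time >= window[1] & tr$time <= window[2]
    if (!any(sel)) stop("empty analysis window")
    r <- tr$rate[, sel, drop = FALSE]
    act <- r >= theta
    act[is.na(act)] <- FALSE
    nA <- colSums(act)
    for (j in seq_along(nA)) {
      k <- nA[j] + 1L
      counts[k] <- counts[k] + 1L
      if (nA[j] > 0) {
        sum_up[k] <- sum_up[k] + mean(r[act[, j], j])
        n_up[k] <- n_up[k] + 1
        all_up <- all_up + mean(r[act[, j], j]); nobs_up <- nobs_up + 1
      }
      if (nA[j] < p) {
        sum_dn[k] <- sum_dn[k] + mean(r[!act[, j], j])
        n_dn[k] <- n_dn[k] + 1
        all_dn <- all_dn + mean(r[!act[, j], j]); nobs_dn <- nobs_dn + 1
      }
    }
  }
  P <- counts / sum(counts)
  names(P) <- 0:p
  rate_up <- ifelse(n_up > 0, sum_up / n_up, NA_real_)
  rate_down <- ifelse(n_dn > 0, sum_dn / n_dn, NA_real_)
  mean_gap <- if (nobs_up > 0) all_up / nobs_up - all_dn / nobs_dn else 0
  list(P = P, nA_star = as.integer(names(which.max(P))),
       rate_up = stats::setNames(rate_up, 0:p),
       rate_down = stats::setNames(rate_down, 0:p),
       low_confidence = stats::setNames(P < p_min, 0:p),
       mean_gap = mean_gap)
}

#' Average duration of cluster activation periods
#'
#' Durations of contiguous supra-threshold epochs within the analysis
#' window, averaged first within a trial and then across trials. Periods
#' clipped by the window boundaries are included at their observed
#' (truncated) duration.
#'
#' @inheritParams activation_summary
#' @return list with `timescale` (s; `NA` when no activation period exists)
#'   and `n_periods`.
#' @export
activation_timescale <- function(traces, window, theta = 15) {
  per_trial <- c()
  n_periods <- 0L
  for (tr in traces) {
    sel <- tr$time >= window[1] & tr$time <= window[2]
    if (!any(sel)) stop("empty analysis window")
    r <- tr$rate[, sel, drop = FALSE]
    act <- r >= theta
    act[is.na(act)] <- FALSE
    durs <- c()
    for (cc in seq_len(nrow(act))) {
      rl <- rle(act[cc, ])
      d <- rl$lengths[rl$values] * tr$dt
      durs <- c(durs, d)
    }
    if (length(durs)) {
      per_trial <- c(per_trial, mean(durs))
      n_periods <- n_periods + length(durs)
    }
  }
  list(timescale = if (length(per_trial)) mean(per_trial) else NA_real_,
       n_periods = n_periods)
}

#' Evoked cluster signal and reliability
#'
#' Characterizes stimulus-evoked cluster dynamics within the peak decoding
#' window. For each trial the cluster signal is the window-average of the
#' difference between the mean rates of targeted and non-targeted clusters;
#' the cluster reliability is the difference between the fractions of
#' targeted and non-targeted clusters that remain activated above baseline
#' (baseline-subtracted rate above `g_thresh`) for at least `persist` s
#' within the window. Also returns the fraction of active clusters that are
#' targeted (spontaneous 100 ms pre-onset vs evoked window) and the
#' targeted-minus-nontargeted difference in the fraction of the window
#' spent activated.
#'
#' @param traces list of [cluster_rates()] outputs, one per evoked trial
#'   (time axis relative to stimulus onset).
#' @param targeted list (per trial) of targeted cluster indices.
#' @param peak_window numeric length-2: the peak decoding window (s).
#' @param baseline_window window for the baseline rate (default
#'   `[-0.8, 0]`).
#' @param theta activation threshold for f_in_T (spikes/s).
#' @param g_thresh baseline-subtracted activation threshold (spikes/s).
#' @param persist minimum persistence (s).
#' @return list with trial-averaged `Cs`, `Cr`, `f_in_T_spont`,
#'   `f_in_T_evoked`, `delta_tau`.
#' @export
evoked_cluster_metrics <- function(traces, targeted, peak_window,
                                   baseline_window = c(-0.8, 0),
                                   theta = 15, g_thresh = 1,
                                   persist = 0.025) {
  p <- nrow(traces[[1]]$rate)
  # trial- and time-averaged baseline rate per cluster
  base <- rowMeans(vapply(traces, function(tr) {
    sel <- tr$time >= baseline_window[1] & tr$time < baseline_window[2]
    rowMeans(tr$rate[, sel, drop = FALSE])
  }, numeric(p)))
  Cs <- Cr <- fT_spont <- fT_evoked <- dtau <- c()
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    targ <- targeted[[i]]
    if (length(targ) == 0L) stop("stimulus with zero targeted clusters")
    ntarg <- setdiff(seq_len(p), targ)
    sel <- tr$time >= peak_window[1] & tr$time <= peak_window[2]
    r <- tr$rate[, sel, drop = FALSE]
    # cluster signal
    Cs <- c(Cs, mean(colMeans(r[targ, , drop = FALSE]) -
                       colMeans(r[ntarg, , drop = FALSE])))
    # persistence of baseline-subtracted activation
    g <- r - base
    act <- g > g_thresh
    persists <- vapply(seq_len(p), function(cc) {
      rl <- rle(act[cc, ])
      any(rl$values & rl$lengths * tr$dt >= persist)
    }, logical(1))
    Cr <- c(Cr, mean(persists[targ]) - mean(persists[ntarg]))
    # fraction of window activated, targeted minus non-targeted
    tau_frac <- rowMeans(act)
    dtau <- c(dtau, mean(tau_frac[targ]) - mean(tau_frac[ntarg]))
    # fraction of active clusters (theta criterion) that are targeted
    f_in <- function(sel2) {
      rr <- tr$rate[, sel2, drop = FALSE] >= theta
      f <- vapply(seq_len(ncol(rr)), function(j) {
        na <- sum(rr[, j])
        if (na == 0) NA_real_ else sum(rr[targ, j]) / na
      }, numeric(1))
      mean(f, na.rm = TRUE)
    }
    fT_spont <- c(fT_spont, f_in(tr$time >= -0.1 & tr$time < 0))
    fT_evoked <- c(fT_evoked, f_in(sel))
  }
  list(Cs = mean(Cs), Cr = mean(Cr),
       f_in_T_spont = mean(fT_spont, na.rm = TRUE),
       f_in_T_evoked = mean(fT_evoked, na.rm = TRUE),
       delta_tau = mean(dtau))
}
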