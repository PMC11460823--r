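# Synthetic extracellular sessions and the data-side preprocessing
# pipeline: pupil cleaning, amplitude-based unit QC, tone-responsiveness,
# pupil-decile partitions, rate-arousal classification, and pupil-balanced
# Fano factors.
#
# The generator emulates the *statistical structure* the analyses consume:
# alternating spontaneous and stimulation blocks, five interleaved pure
# tones (25 ms, 775 ms ISI), a slowly-varying pupil trace at 1 ms
# resolution, treadmill speed at 100 Hz, doubly-stochastic spiking whose
# spontaneous rate and/or evoked gain depend on pupil through per-unit gain
# curves (monotone up/down, inverted-U, or flat), per-spike template
# amplitudes with optional injected QC defects, and injected pupil
# artifacts. Ground-truth generative parameters are stored for recovery
# tests.

#' Configuration for a synthetic recording session
#'
#' @param n_units number of units.
#' @param n_blocks number of spontaneous+evoked block pairs.
#' @param spont_block_s,evoked_block_s block durations (s). The experimental
#'   protocol uses 300 s and 1500 s; defaults are scaled down for tractable
#'   examples.
#' @param tone_freqs_khz tone frequencies (kHz).
#' @param tone_dur,isi tone duration and inter-stimulus interval (s).
#' @param base_rate_mean,base_rate_sd lognormal parameters of unit base
#'   rates (spikes/s).
#' @param gain_shapes character vector recycled over units: each of
#'   `"up"`, `"down"`, `"invU"`, `"flat"`.
#' @param gain_strength peak-to-trough modulation depth of the pupil gain.
#' @param gain_on which response components the pupil gain multiplies:
#'   subset of `c("spont", "evoked")`.
#' @param evoked_gain mean evoked-response amplitude (multiple of base
#'   rate) for a unit's preferred tone.
#' @param slow_noise_sd log-SD of the slow multiplicative rate noise.
#' @param slow_noise_tau timescale of the slow rate noise (s).
#' @param pupil_tau,pupil_sd OU timescale (s) and spread of the latent
#'   pupil process.
#' @param artifact_rate rate of injected pupil jump artifacts (per s).
#' @param qc_bimodal_frac,qc_drift_frac fractions of units with injected
#'   amplitude defects.
#' @param amp_cv coefficient of variation of template amplitudes.
#' @return An object of class `session_config`.
#' @export
session_config <- function(n_units = 30, n_blocks = 2,
                           spont_block_s = 60, evoked_block_s = 120,
                           tone_freqs_khz = c(2, 4, 8, 16, 32),
                           tone_dur = 0.025, isi = 0.775,
                           base_rate_mean = 5, base_rate_sd = 0.5,
                           gain_shapes = "flat", gain_strength = 0.8,
                           gain_on = c("spont", "evoked"),
                           evoked_gain = 2, slow_noise_sd = 0.1,
                           slow_noise_tau = 5,
                           pupil_tau = 20, pupil_sd = 0.18,
                           artifact_rate = 0, qc_bimodal_frac = 0,
                           qc_drift_frac = 0, amp_cv = 0.05) {
  stopifnot(n_units >= 1, n_blocks >= 1)
  structure(as.list(environment()), class = "session_config")
}

.gain_curve <- function(shape, g) {
  switch(shape,
         up = function(x) 1 + g * (x - 0.5),
         down = function(x) 1 - g * (x - 0.5),
         invU = function(x) 1 - g / 2 + g * (1 - 4 * (x - 0.5)^2),
         flat = function(x) rep(1, length(x)),
         stop("unknown gain shape: ", shape))
}

#' Generate a synthetic Neuropixels-style session
#'
#' See [session_config()] for the generative knobs. Spiking is an
#' inhomogeneous Poisson process on a 1 ms grid whose rate is
#' `base * gain(pupil percentile) * slow_noise * (1 + evoked kernel)`;
#' gain curves are evaluated on the session-relative percentile of the
#' pupil trace, and the pupil gain
#' multiplies the spontaneous rate and/or the evoked component according to
#' `gain_on`. Tone onsets tile the evoked blocks (`tone_dur + isi` period)
#' with frequencies drawn uniformly.
#'
#' @param config a [session_config()].
#' @param seed integer seed; fixed seeds give identical sessions.
#' @return An object of class `synthetic_session`: `spikes` (`data.table`:
#'   `unit`, `time`), `pupil` (`time`, `diameter` in percent of max,
#'   `valid`), `running` (`time`, `speed`), `events` (`time`, `freq`),
#'   `blocks`, `amplitudes` (`unit`, `time`, `amp`), `truth` (per-unit
#'   generative parameters and injected defects), `config`.
#' @export
generate_session <- function(config, seed = 1) {
  set.seed(seed)
  cf <- config
  block_len <- cf$spont_block_s + cf$evoked_block_s
  T_total <- cf$n_blocks * block_len
  dt <- 0.001
  nt <- round(T_total / dt)
  tgrid <- (seq_len(nt) - 1) * dt
  # --- latent pupil: OU at 10 ms, interpolated to 1 ms, squashed to (0,1)
  dt_ou <- 0.01
  n_ou <- ceiling(T_total / dt_ou) + 1L
  x <- numeric(n_ou)
  x[1] <- stats::rnorm(1, 0, cf$pupil_sd)
  a <- exp(-dt_ou / cf$pupil_tau)
  innov <- stats::rnorm(n_ou - 1, 0, cf$pupil_sd * sqrt(1 - a^2))
  for (i in 2:n_ou) x[i] <- a * x[i - 1] + innov[i - 1]
  pupil01 <- stats::plogis(x / cf$pupil_sd * 1.2)
  pupil <- stats::approx(seq(0, by = dt_ou, length.out = n_ou), pupil01,
                         xout = tgrid, rule = 2)$y
  # injected jump artifacts (step up for ~80 ms, then back)
  art_times <- c()
  if (cf$artifact_rate > 0) {
    n_art <- stats::rpois(1, cf$artifact_rate * T_total)
    art_times <- sort(stats::runif(n_art, 1, T_total - 1))
    for (ta in art_times) {
      i0 <- round(ta / dt); i1 <- min(i0 + 80, nt)
      pupil[i0:i1] <- pmin(pupil[i0:i1] + 0.25, 1.2)
    }
  }
  # --- blocks and tone events
  blocks <- data.frame(
    start = (seq_len(cf$n_blocks) - 1) * block_len,
    spont_end = (seq_len(cf$n_blocks) - 1) * block_len + cf$spont_block_s,
    end = seq_len(cf$n_blocks) * block_len)
  period <- cf$tone_dur + cf$isi
  ev <- list()
  for (b in seq_len(cf$n_blocks)) {
    onsets <- seq(blocks$spont_end[b] + 0.5, blocks$end[b] - period,
                  by = period)
    ev[[b]] <- data.frame(time = onsets,
                          freq = sample(cf$tone_freqs_khz,
                                        length(onsets), replace = TRUE))
  }
  events <- do.call(rbind, ev)
  # --- per-unit generative parameters
  shapes <- rep_len(cf$gain_shapes, cf$n_units)
  base <- stats::rlnorm(cf$n_units, log(cf$base_rate_mean), cf$base_rate_sd)
  tuning <- matrix(stats::runif(cf$n_units * length(cf$tone_freqs_khz),
                                0, 1)^2, cf$n_units)
  tuning <- tuning / apply(tuning, 1, max)
  amp_mean <- stats::runif(cf$n_units, 8, 20)
  n_def_bi <- round(cf$qc_bimodal_frac * cf$n_units)
  n_def_dr <- round(cf$qc_drift_frac * cf$n_units)
  defect <- rep("none", cf$n_units)
  if (n_def_bi > 0) defect[seq_len(n_def_bi)] <- "bimodal"
  if (n_def_dr > 0) defect[n_def_bi + seq_len(n_def_dr)] <- "drift"
  # evoked kernel on the 1 ms grid (rise 5 ms, decay 30 ms, 100 ms support)
  ku <- seq(0, 0.1, by = dt)
  kern <- (exp(-ku / 0.03) - exp(-ku / 0.005))
  kern <- kern / max(kern)
  ev_idx <- round(events$time / dt)
  freq_idx <- match(events$freq, cf$tone_freqs_khz)
  # spontaneous/evoked pupil gain factors
  spikes <- vector("list", cf$n_units)
  amps <- vector("list", cf$n_units)
  # gain curves act on the session-relative pupil percentile, so the
  # configured shapes span the observed arousal range symmetrically
  pupil_pct <- (rank(pupil) - 0.5) / length(pupil)
  for (u in seq_len(cf$n_units)) {
    gain <- .gain_curve(shapes[u], cf$gain_strength)(pupil_pct)
    g_spont <- if ("spont" %in% cf$gain_on) gain else rep(1, nt)
    g_evoked <- if ("evoked" %in% cf$gain_on) gain else rep(1, nt)
    # slow multiplicative log-OU noise, 1 s resolution
    n_sl <- ceiling(T_total) + 1L
    sl <- numeric(n_sl)
    asl <- exp(-1 / cf$slow_noise_tau)
    sl[1] <- stats::rnorm(1, 0, cf$slow_noise_sd)
    for (i in 2:n_sl)
      sl[i] <- asl * sl[i - 1] +
        stats::rnorm(1, 0, cf$slow_noise_sd * sqrt(1 - asl^2))
    slow <- exp(stats::approx(seq(0, by = 1, length.out = n_sl), sl,
                              xout = tgrid, rule = 2)$y)
    rate <- base[u] * g_spont * slow
    # evoked additions
    evk <- numeric(nt)
    for (e in seq_along(ev_idx)) {
      i0 <- ev_idx[e] + 1L
      i1 <- min(i0 + length(kern) - 1L, nt)
      seg <- seq_len(i1 - i0 + 1L)
      evk[i0:i1] <- evk[i0:i1] +
        cf$evoked_gain * tuning[u, freq_idx[e]] * kern[seg] *
        g_evoked[i0] / pmax(g_spont[i0], 1e-6)
    }
    rate <- rate * (1 + evk)
    n_sp <- stats::rpois(nt, rate * dt)
    st <- tgrid[n_sp > 0]
    st <- rep(st, n_sp[n_sp > 0]) + stats::runif(sum(n_sp), 0, dt)
    st <- sort(st)
    spikes[[u]] <- data.table::data.table(unit = u, time = st)
    # template amplitudes per spike
    amp <- amp_mean[u] * (1 + cf$amp_cv * stats::rnorm(length(st)))
    if (defect[u] == "bimodal") {
      # second amplitude mode in the middle 40% of the session
      inwin <- st > 0.3 * T_total & st < 0.7 * T_total
      flip <- inwin & stats::runif(length(st)) < 0.5
      amp[flip] <- amp[flip] * 0.45
    } else if (defect[u] == "drift") {
      # drift into the detection floor: declines over the third quarter of
      # the session, then amplitudes pile up at the floor (clipped, as
      # thresholded spike detection would produce)
      u01 <- pmax((st - 0.5 * T_total) / (0.5 * T_total), 0)
      amp <- pmax(amp * pmax(1 - 2 * u01, 0), 0.1 * amp_mean[u])
    }
    amps[[u]] <- data.table::data.table(unit = u, time = st, amp = amp)
  }
  run_dt <- 0.01
  ngrid_run <- round(T_total / run_dt)
  bout <- stats::rbinom(ngrid_run, 1, 0.002)
  speed <- stats::filter(bout * stats::runif(ngrid_run, 5, 15),
                         rep(1, 200), sides = 1)
  speed[is.na(speed)] <- 0
  structure(list(
    spikes = data.table::rbindlist(spikes),
    pupil = data.table::data.table(time = tgrid,
                                   diameter = 100 * pupil / max(pupil),
                                   valid = TRUE),
    running = data.table::data.table(time = (seq_len(ngrid_run) - 1) * run_dt,
                                     speed = as.numeric(speed)),
    events = events, blocks = blocks,
    amplitudes = data.table::rbindlist(amps),
    truth = list(shapes = shapes, base = base, tuning = tuning,
                 defect = defect, artifact_times = art_times,
                 pupil_latent = NULL),
    config = cf), class = "synthetic_session")
}

#' Clean a raw pupil trace
#'
#' Artifact removal, smoothing, and renormalization: samples around
#' unnaturally-sharp jumps (normalized absolute difference between
#' consecutive 1 ms samples above `thresh`) are masked from 250 ms before
#' to 500 ms after the jump; the trace is then smoothed with a 1/30 s
#' moving average and renormalized to its maximum.
#'
#' @param diameter numeric raw trace (arbitrary units, 1 ms resolution).
#' @param dt sample interval (s).
#' @param thresh jump threshold on the max-normalized trace.
#' @param mask_before,mask_after masking window around a jump (s).
#' @param smooth_s moving-average length (s).
#' @return `data.table` with `time`, `diameter` (percent of max; `NA` in
#'   masked gaps), `valid`.
#' @export
clean_pupil <- function(diameter, dt = 0.001, thresh = 0.08,
                        mask_before = 0.25, mask_after = 0.5,
                        smooth_s = 1 / 30) {
  n <- length(diameter)
  norm <- diameter / max(diameter, na.rm = TRUE)
  jumps <- which(abs(diff(norm)) > thresh)
  valid <- rep(TRUE, n)
  for (j in jumps) {
    i0 <- max(1L, j - round(mask_before / dt))
    i1 <- min(n, j + round(mask_after / dt))
    valid[i0:i1] <- FALSE
  }
  if (!any(valid)) stop("entire trace masked")
  x <- diameter
  x[!valid] <- NA
  k <- max(1L, round(smooth_s / dt))
  # pad the ends so the centered moving average is defined at the edges
  pad <- k %/% 2 + 1L
  xp <- c(rep(x[1], pad), x, rep(x[n], pad))
  smp <- data.table::frollmean(xp, k, align = "center", na.rm = TRUE,
                               hasNA = TRUE)
  sm <- smp[pad + seq_len(n)]
  sm[!valid] <- NA
  out <- 100 * sm / max(sm, na.rm = TRUE)
  data.table::data.table(time = (seq_len(n) - 1) * dt, diameter = out,
                         valid = valid & !is.na(out))
}

# symmetric percent difference used by the amplitude QC
.pct_diff <- function(a, b) 200 * abs(a - b) / (a + b)

# peak locations/heights of a kernel density estimate (Gaussian kernel,
# Scott's-rule bandwidth)
.kde_peaks <- function(x) {
  if (length(x) < 5) return(NULL)
  if (stats::sd(x) == 0) return(list(loc = x[1], height = Inf))
  d <- stats::density(x, bw = "nrd")
  y <- d$y
  pk <- which(y > c(-Inf, y[-length(y)]) & y >= c(y[-1], -Inf))
  if (!length(pk)) return(NULL)
  ord <- order(y[pk], decreasing = TRUE)
  list(loc = d$x[pk][ord], height = y[pk][ord])
}

#' Amplitude-based unit quality control
#'
#' Applies three rejection rules: (1) mean firing rate below `rate_floor`;
#' (2) multimodal template-amplitude distributions — in non-overlapping
#' windows (default 5 min), a window is flagged when the KDE of the
#' amplitudes has two or more peaks whose height ratio is at most
#' `height_ratio_max` and whose percent location difference is at least
#' `loc_diff_min`; the unit is rejected when at least `frac_windows` of the
#' windows are flagged; (3) drift towards/away from the noise floor — a
#' window is "near floor" when the tallest KDE peak sits within
#' `floor_pct_max` percent of the smallest recorded amplitude; the unit is
#' rejected when more than `frac_windows` (but not all) windows are near
#' the floor and the range of tallest-peak locations across windows is at
#' least `drift_range_min` percent.
#'
#' @param spike_times spike times of the unit (s).
#' @param amp template amplitude per spike.
#' @param session_length recording length (s).
#' @param window_s QC window length (s).
#' @param rate_floor minimum mean rate (spikes/s).
#' @param height_ratio_max,loc_diff_min multimodality cut values.
#' @param floor_pct_max,drift_range_min noise-floor cut values.
#' @param frac_windows flagged-window fraction triggering rejection.
#' @return list with `keep` (logical), `reasons` (character vector),
#'   per-window flags, and summary fractions.
#' @export
unit_qc <- function(spike_times, amp, session_length, window_s = 300,
                    rate_floor = 0.25, height_ratio_max = 10,
                    loc_diff_min = 40, floor_pct_max = 15,
                    drift_range_min = 25, frac_windows = 0.1) {
  reasons <- character(0)
  rate <- length(spike_times) / session_length
  if (rate < rate_floor) reasons <- c(reasons, "low_rate")
  wins <- seq(0, session_length - window_s + 1e-9, by = window_s)
  if (length(wins) < 1)
    return(list(keep = !length(reasons), reasons = c(reasons,
                "insufficient_data"), multimodal_frac = NA,
                near_floor_frac = NA))
  multimodal <- near_floor <- logical(length(wins))
  top_loc <- rep(NA_real_, length(wins))
  floor_amp <- min(amp)
  for (w in seq_along(wins)) {
    sel <- spike_times >= wins[w] & spike_times < wins[w] + window_s
    pk <- .kde_peaks(amp[sel])
    if (is.null(pk)) next
    top_loc[w] <- pk$loc[1]
    if (length(pk$loc) >= 2) {
      ratio <- pk$height[1] / pk$height[2]
      ld <- .pct_diff(pk$loc[1], pk$loc[2])
      multimodal[w] <- ratio <= height_ratio_max && ld >= loc_diff_min
    }
    near_floor[w] <- .pct_diff(pk$loc[1], floor_amp) <= floor_pct_max ||
      pk$loc[1] <= floor_amp * (1 + floor_pct_max / 100)
  }
  mm_frac <- mean(multimodal)
  nf_frac <- mean(near_floor)
  if (mm_frac >= frac_windows) reasons <- c(reasons, "multimodal_amplitude")
  drift_range <- if (sum(!is.na(top_loc)) >= 2)
    .pct_diff(max(top_loc, na.rm = TRUE), min(top_loc, na.rm = TRUE))
  else 0
  if (nf_frac > frac_windows && nf_frac < 1 &&
      drift_range >= drift_range_min)
    reasons <- c(reasons, "noise_floor_drift")
  list(keep = !length(reasons), reasons = reasons,
       multimodal = multimodal, near_floor = near_floor,
       multimodal_frac = mm_frac, near_floor_frac = nf_frac,
       drift_range = drift_range)
}

#' Tone-responsiveness test
#'
#' For each tone, compares spike counts in 100 ms windows slid at 1 ms
#' steps through the evoked period (window end in `(0, evoked_s]` after
#' onset) against the pooled counts of all baseline windows (fully inside
#' the `baseline_s` pre-onset period), using the Mann-Whitney U test with
#' Bonferroni correction over evoked bins. The unit is responsive to a tone
#' when corrected significance persists for at least `min_run_s`.
#'
#' @param spike_times unit spike times (s).
#' @param events data.frame with `time` (onsets, s) and `freq`.
#' @param window_s sliding-window length (s).
#' @param step_s window increment (s).
#' @param evoked_s,baseline_s evoked and baseline period lengths (s).
#' @param alpha significance level after correction.
#' @param min_run_s minimum run of consecutive significant bins (s).
#' @return named logical vector (one per tone frequency), with attribute
#'   `p_matrix` (corrected p-values, tones x evoked bins).
#' @export
tone_responsiveness <- function(spike_times, events, window_s = 0.1,
                                step_s = 0.001, evoked_s = 0.2,
                                baseline_s = 0.2, alpha = 0.05,
                                min_run_s = 0.005) {
  freqs <- sort(unique(events$freq))
  ends_ev <- seq(step_s, evoked_s, by = step_s)
  starts_base <- seq(-baseline_s, -window_s, by = step_s)
  res <- stats::setNames(logical(length(freqs)), freqs)
  pmat <- matrix(NA_real_, length(freqs), length(ends_ev))
  count_in <- function(onsets, lo, hi) {
    vapply(onsets, function(o)
      sum(spike_times >= o + lo & spike_times < o + hi), numeric(1))
  }
  for (fi in seq_along(freqs)) {
    onsets <- events$time[events$freq == freqs[fi]]
    if (length(onsets) < 2) stop("need >= 2 trials per tone")
    base_counts <- unlist(lapply(starts_base, function(s)
      count_in(onsets, s, s + window_s)))
    pv <- vapply(ends_ev, function(e) {
      evc <- count_in(onsets, e - window_s, e)
      if (all(evc == base_counts[1]) && length(unique(base_counts)) == 1L)
        return(1)
      suppressWarnings(stats::wilcox.test(evc, base_counts)$p.value)
    }, numeric(1))
    p_adj <- pmin(pv * length(ends_ev), 1)
    pmat[fi, ] <- p_adj
    rl <- rle(p_adj < alpha)
    res[fi] <- any(rl$values & rl$lengths >= round(min_run_s / step_s))
  }
  attr(res, "p_matrix") <- pmat
  res
}

#' Partition trials or windows into pupil deciles
#'
#' Splits observations into ten equally-sized groups by the deciles of
#' their pupil values, optionally excluding locomotion observations first
#' and balancing tone counts within each decile by subsampling.
#'
#' @param pupil numeric pupil value per observation (pre-stimulus average
#'   for evoked trials).
#' @param labels optional tone label per observation; when given, each
#'   decile is subsampled so all tones appear equally often.
#' @param exclude logical mask of observations to drop (e.g. locomotion).
#' @param n_part number of partitions.
#' @param seed RNG seed for the balancing subsample.
#' @return list with `partition` (integer 1..n per observation, `NA` for
#'   excluded/unsampled), `decile_mean_pupil`.
#' @export
pupil_decile_partition <- function(pupil, labels = NULL, exclude = NULL,
                                   n_part = 10, seed = 1) {
  set.seed(seed)
  n <- length(pupil)
  keep <- if (is.null(exclude)) rep(TRUE, n) else !exclude
  idx <- which(keep)
  if (length(unique(pupil[idx])) < n_part)
    stop("degenerate pupil distribution: too few distinct values")
  ord <- idx[order(pupil[idx])]
  part <- rep(NA_integer_, n)
  sizes <- rep(floor(length(ord) / n_part), n_part)
  # leftover observations are dropped from the top to keep groups equal
  part[ord[seq_len(sum(sizes))]] <- rep(seq_len(n_part), sizes)
  if (!is.null(labels)) {
    for (d in seq_len(n_part)) {
      sel <- which(part == d)
      tab <- table(labels[sel])
      n_min <- min(tab)
      keep_sel <- unlist(lapply(split(sel, labels[sel]), function(ii)
        ii[sample.int(length(ii), n_min)]))
      part[setdiff(sel, keep_sel)] <- NA_integer_
    }
  }
  dm <- vapply(seq_len(n_part), function(d)
    mean(pupil[which(part == d)]), numeric(1))
  list(partition = part, decile_mean_pupil = dm)
}

#' Classify units by the sign of their rate-arousal relationship
#'
#' Spearman correlation between per-condition average firing rates and the
#' condition value (mean pupil per decile, or modulation strength in the
#' models); units with p < alpha are classified by the sign of the
#' correlation, others as `"none"`.
#'
#' @param rates units x conditions matrix of average rates.
#' @param condition_values numeric vector (one per condition).
#' @param alpha significance level.
#' @return data.frame with `unit`, `r`, `p`, `class`; attribute
#'   `fractions` = c(positive, negative).
#' @export
rate_arousal_classification <- function(rates, condition_values,
                                        alpha = 0.05) {
  if (length(condition_values) < 3) stop("need >= 3 conditions")
  out <- data.frame(unit = seq_len(nrow(rates)), r = NA_real_,
                    p = NA_real_, class = "none",
                    stringsAsFactors = FALSE)
  for (u in seq_len(nrow(rates))) {
    y <- rates[u, ]
    if (stats::sd(y) == 0) next
    ct <- suppressWarnings(
      stats::cor.test(y, condition_values, method = "spearman"))
    out$r[u] <- unname(ct$estimate)
    out$p[u] <- ct$p.value
    if (!is.na(ct$p.value) && ct$p.value < alpha)
      out$class[u] <- if (ct$estimate > 0) "positive" else "negative"
  }
  attr(out, "fractions") <- c(positive = mean(out$class == "positive"),
                              negative = mean(out$class == "negative"))
  out
}

#' Pupil-balanced Fano factors from a session
#'
#' Splits spontaneous blocks into 100 ms windows binned by mean pupil
#' diameter (bins given by their upper edges in percent of max), balances
#' the number of windows per bin by random subsampling, and computes each
#' cell's spontaneous Fano factor per bin, averaged across subsamples.
#' Cells with a spontaneous rate below `rate_floor` in any bin are
#' excluded.
#'
#' @param session a `synthetic_session` (or compatible list).
#' @param bin_edges upper bin edges (percent of max).
#' @param n_subsamples random subsamples to average.
#' @param window_s spontaneous window length (s).
#' @param min_windows minimum windows per bin; fewer means the session
#'   does not sample a broad pupil range and `NULL` is returned.
#' @param rate_floor spontaneous-rate inclusion threshold (spikes/s).
#' @param units optional subset of units.
#' @param seed RNG seed.
#' @return list with `FF` (units x bins, `NA` for excluded cells),
#'   `bin_upper`, `n_windows_per_bin`, `included`; or `NULL` if any bin is
#'   undersampled.
#' @export
pupil_balanced_fano <- function(session,
                                bin_edges = c(25, 35, 45, 55, 65, 75, 100),
                                n_subsamples = 100, window_s = 0.1,
                                min_windows = 25, rate_floor = 1,
                                units = NULL, seed = 1) {
  set.seed(seed)
  if (is.null(units)) units <- sort(unique(session$spikes$unit))
  # spontaneous windows
  wins <- list()
  for (b in seq_len(nrow(session$blocks))) {
    s0 <- session$blocks$start[b]; s1 <- session$blocks$spont_end[b]
    starts <- seq(s0, s1 - window_s, by = window_s)
    wins[[b]] <- starts
  }
  starts <- unlist(wins)
  pup <- session$pupil
  pmean <- vapply(starts, function(s) {
    sel <- pup$time >= s & pup$time < s + window_s
    mean(pup$diameter[sel], na.rm = TRUE)
  }, numeric(1))
  lower <- c(0, bin_edges[-length(bin_edges)])
  bin <- findInterval(pmean, c(lower, Inf), rightmost.closed = FALSE)
  bin[bin > length(bin_edges)] <- length(bin_edges)
  counts_tab <- table(factor(bin, levels = seq_along(bin_edges)))
  n_bal <- min(counts_tab)
  if (n_bal < min_windows) return(NULL)
  # per-unit counts in each window
  cmat <- matrix(0L, length(units), length(starts))
  sp <- session$spikes[session$spikes$unit %in% units]
  for (w in seq_along(starts)) {
    sel <- sp$time >= starts[w] & sp$time < starts[w] + window_s
    if (!any(sel)) next
    tb <- table(factor(sp$unit[sel], levels = units))
    cmat[, w] <- as.integer(tb)
  }
  nb <- length(bin_edges)
  FF <- matrix(0, length(units), nb)
  rate_bin <- matrix(0, length(units), nb)
  for (bi in seq_len(nb)) {
    inb <- which(bin == bi)
    acc <- matrix(0, length(units), n_subsamples)
    for (s in seq_len(n_subsamples)) {
      sub <- inb[sample.int(length(inb), n_bal)]
      m <- rowMeans(cmat[, sub, drop = FALSE])
      v <- apply(cmat[, sub, drop = FALSE], 1, stats::var)
      acc[, s] <- ifelse(m > 0, v / m, NA_real_)
    }
    FF[, bi] <- rowMeans(acc, na.rm = TRUE)
    rate_bin[, bi] <- rowMeans(cmat[, inb, drop = FALSE]) / window_s
  }
  included <- apply(rate_bin >= rate_floor, 1, all)
  FF[!included, ] <- NA_real_
  list(FF = FF, bin_upper = bin_edges,
       n_windows_per_bin = as.integer(counts_tab), n_balanced = n_bal,
       included = included, units = units)
}
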