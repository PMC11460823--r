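# Session-level analyses: pupil-conditioned decoding and rate-arousal
# classification, composing the preprocessing and coding modules.

#' Tone decoding per pupil-decile partition of a session
#'
#' Extracts evoked trials (tone events with a full analysis span inside the
#' recording), computes each trial's pre-stimulus pupil diameter, partitions
#' trials into pupil deciles balanced per tone, and decodes tone identity
#' within each partition, returning the peak accuracy per decile.
#'
#' @param session a `synthetic_session`.
#' @param window,step,span sliding-window parameters.
#' @param pre_window pre-onset span (s) over which the trial's pupil
#'   diameter is averaged.
#' @param n_folds,n_repeats,reg passed to [decode_timecourse()].
#' @param exclude_running exclude trials whose mean treadmill speed over
#'   the pre-stimulus window exceeds 1 cm/s.
#' @param seed RNG seed (balancing + cross-validation folds).
#' @return data.frame with `decile`, `pupil` (decile mean diameter, % max),
#'   `peak_accuracy`, `n_trials`.
#' @export
session_decode_by_pupil <- function(session, window = 0.1, step = 0.02,
                                    span = c(-0.1, 0.6), pre_window = 0.1,
                                    n_folds = 5, n_repeats = 5, reg = 1e-4,
                                    exclude_running = FALSE, seed = 1) {
  ev <- session$events
  units <- sort(unique(session$spikes$unit))
  pup <- session$pupil
  # pupil per trial (pre-onset average); index arithmetic on the 1 ms grid
  dt_p <- pup$time[2] - pup$time[1]
  pre_n <- round(pre_window / dt_p)
  onset_idx <- round(ev$time / dt_p)
  pupil_tr <- vapply(onset_idx, function(i)
    mean(pup$diameter[max(1, i - pre_n):i], na.rm = TRUE), numeric(1))
  excl <- is.na(pupil_tr)
  if (exclude_running) {
    run <- session$running
    dt_r <- run$time[2] - run$time[1]
    rid <- round(ev$time / dt_r)
    rn <- round(pre_window / dt_r)
    spd <- vapply(rid, function(i)
      mean(run$speed[max(1, i - rn):i]), numeric(1))
    excl <- excl | spd > 1
  }
  part <- pupil_decile_partition(pupil_tr, labels = ev$freq,
                                 exclude = excl, seed = seed)
  # spike counts relative to onset, one "trial" per tone event
  sp <- session$spikes
  out <- list()
  for (d in seq_len(10)) {
    sel <- which(part$partition == d)
    if (length(sel) < n_folds * length(unique(ev$freq))) next
    # build a per-trial spike table restricted to the span
    rows <- lapply(sel, function(tr) {
      t0 <- ev$time[tr]
      ss <- sp[sp$time >= t0 + span[1] & sp$time < t0 + span[2]]
      if (!nrow(ss)) return(NULL)
      data.table::data.table(unit = ss$unit, time = ss$time - t0, trial = tr)
    })
    spikes_d <- data.table::rbindlist(rows[!vapply(rows, is.null,
                                                   logical(1))])
    cts <- sliding_counts(spikes_d, trials = sel, units = units,
                          window = window, step = step, span = span)
    labels <- ev$freq[sel]
    dec <- decode_timecourse(cts, labels, n_folds = n_folds,
                             n_repeats = n_repeats, reg = reg,
                             seed = seed + d)
    out[[length(out) + 1L]] <- data.frame(
      decile = d, pupil = part$decile_mean_pupil[d],
      peak_accuracy = dec$peak_accuracy, n_trials = length(sel))
  }
  do.call(rbind, out)
}

#' Rate-arousal classification of a session's units
#'
#' Splits spontaneous blocks into 100 ms windows, bins them by the deciles
#' of their pupil-diameter distribution, computes each unit's average rate
#' per decile and classifies units by the Spearman correlation between the
#' per-decile rates and the per-decile mean pupil diameters.
#'
#' @param session a `synthetic_session`.
#' @param window_s spontaneous window length (s).
#' @param alpha significance level.
#' @param seed RNG seed.
#' @return the [rate_arousal_classification()] result (attribute
#'   `fractions` holds the positive/negative fractions).
#' @export
session_modulation <- function(session, window_s = 0.1, alpha = 0.05,
                               seed = 1) {
  units <- sort(unique(session$spikes$unit))
  starts <- unlist(lapply(seq_len(nrow(session$blocks)), function(b)
    seq(session$blocks$start[b], session$blocks$spont_end[b] - window_s,
        by = window_s)))
  pup <- session$pupil
  dt_p <- pup$time[2] - pup$time[1]
  i0 <- round(starts / dt_p) + 1L
  i1 <- i0 + round(window_s / dt_p) - 1L
  pmean <- vapply(seq_along(starts), function(k)
    mean(pup$diameter[i0[k]:i1[k]], na.rm = TRUE), numeric(1))
  part <- pupil_decile_partition(pmean, seed = seed)
  sp <- session$spikes
  widx <- findInterval(sp$time, starts)
  inwin <- widx >= 1 & sp$time < starts[pmax(widx, 1)] + window_s
  cnt <- table(factor(sp$unit[inwin], levels = units),
               factor(widx[inwin], levels = seq_along(starts)))
  rates <- matrix(0, length(units), 10)
  for (d in seq_len(10)) {
    sel <- which(part$partition == d)
    rates[, d] <- rowMeans(cnt[, sel, drop = FALSE]) / window_s
  }
  rate_arousal_classification(rates, part$decile_mean_pupil, alpha = alpha)
}
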