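# Spike-train variability: rate-normalized multitaper spectra of binned
# point processes, low-frequency power, and spontaneous/evoked Fano
# factors.

# --- discrete prolate spheroidal sequences -------------------------------
# Top-K eigenvectors of the standard symmetric tridiagonal commuting matrix
# (diagonal ((N-1)/2 - t)^2 cos(2 pi W), off-diagonal t (N - t) / 2),
# computed by Lanczos with full reorthogonalization; the extreme Ritz pairs
# converge quickly and are the DPSS in index order.
.dpss_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' @param n sequence length (bins).
#' @param nw time-bandwidth product.
#' @param k number of tapers (conventionally `2 * nw - 1`).
#' @return `n x k` matrix of orthonormal tapers, each with unit sum of
#'   squares and positive leading lobe.
#' @export
dpss_tapers <- function(n, nw = 5, k = 2 * nw - 1) {
  key <- paste(n, nw, k, sep = "_")
  if (!is.null(.dpss_cache[[key]])) return(.dpss_cache[[key]])
  w <- nw / n
  t <- seq_len(n) - 1
  diag_v <- ((n - 1) / 2 - t)^2 * cos(2 * pi * w)
  off_v <- (seq_len(n - 1)) * (n - seq_len(n - 1)) / 2
  matvec <- function(x) {
    y <- diag_v * x
    y[-n] <- y[-n] + off_v * x[-1]
    y[-1] <- y[-1] + off_v * x[-n]
    y
  }
  m <- min(max(4L * k, 40L), n)
  Q <- matrix(0, n, m)
  alpha <- beta <- numeric(m)
  # deterministic smooth start vector (good overlap with the leading taper)
  q <- sin(pi * (t + 1) / (n + 1)); q <- q / sqrt(sum(q^2))
  Q[, 1] <- q
  for (j in seq_len(m)) {
    v <- matvec(Q[, j])
    alpha[j] <- sum(Q[, j] * v)
    v <- v - alpha[j] * Q[, j]
    if (j > 1) v <- v - beta[j - 1] * Q[, j - 1]
    v <- v - Q[, seq_len(j), drop = FALSE] %*%
      crossprod(Q[, seq_len(j), drop = FALSE], v)  # reorthogonalize
    b <- sqrt(sum(v^2))
    if (j < m) {
      if (b < 1e-12) { m <- j; break }
      beta[j] <- b
      Q[, j + 1] <- v / b
    }
  }
  Tm <- diag(alpha[seq_len(m)])
  for (j in seq_len(m - 1)) Tm[j, j + 1] <- Tm[j + 1, j] <- beta[j]
  e <- eigen(Tm, symmetric = TRUE)
  tapers <- Q[, seq_len(m), drop = FALSE] %*% e$vectors[, seq_len(k)]
  # normalize and fix sign conventions (symmetric tapers positive mean,
  # antisymmetric tapers positive initial slope)
  for (j in seq_len(k)) {
    tapers[, j] <- tapers[, j] / sqrt(sum(tapers[, j]^2))
    s <- sum(tapers[, j])
    if (abs(s) > 1e-8) {
      if (s < 0) tapers[, j] <- -tapers[, j]
    } else if (tapers[2, j] - tapers[1, j] < 0) {
      tapers[, j] <- -tapers[, j]
    }
  }
  .dpss_cache[[key]] <- tapers
  tapers
}

#' Rate-normalized multitaper spectrum of spike trains
#'
#' Bins each trial's spike train at `dt` resolution, removes the mean
#' (the rate line at zero frequency), applies `2 TW - 1` Slepian tapers,
#' and averages the squared Fourier magnitudes. Each trial's estimate is
#' divided by its mean bin count, which equals normalizing by the spectrum
#' of a Poisson process with the same rate (a homogeneous Poisson train has
#' `S_norm = 1` at all frequencies). Trials without spikes are excluded.
#'
#' @param spike_times list of numeric vectors (one per trial), times in s
#'   within `[0, trial_length]`.
#' @param trial_length trial duration (s).
#' @param tw time-bandwidth product.
#' @param dt bin width (s; 1 ms convention).
#' @return An object of class `spectral_estimate`: `freq` (Hz), `S_norm`,
#'   `n_trials_used`, `n_excluded`, `n_tapers`, `tw`.
#' @export
multitaper_point_spectrum <- function(spike_times, trial_length, tw = 5,
                                      dt = 0.001) {
  n <- round(trial_length / dt)
  k <- 2 * tw - 1
  tapers <- dpss_tapers(n, tw, k)
  nfreq <- floor(n / 2) + 1L
  freq <- (seq_len(nfreq) - 1) / (n * dt)
  acc <- numeric(nfreq)
  used <- 0L
  excluded <- 0L
  for (st in spike_times) {
    st <- st[st >= 0 & st < trial_length]
    if (length(st) == 0L) { excluded <- excluded + 1L; next }
    x <- tabulate(floor(st / dt) + 1L, nbins = n)
    xc <- x - mean(x)
    S <- numeric(nfreq)
    for (j in seq_len(k)) {
      ft <- stats::fft(tapers[, j] * xc)
      S <- S + Mod(ft[seq_len(nfreq)])^2
    }
    S <- S / k
    acc <- acc + S / mean(x)
    used <- used + 1L
  }
  if (used == 0L) stop("no trials with spikes")
  structure(list(freq = freq, S_norm = acc / used, n_trials_used = used,
                 n_excluded = excluded, n_tapers = k, tw = tw),
            class = "spectral_estimate")
}

#' Band-averaged low-frequency power
#'
#' Arithmetic mean of the rate-normalized spectrum over the grid
#' frequencies inside `band` (endpoints inclusive; the conventional band is
#' 1-4 Hz).
#'
#' @param estimate a `spectral_estimate`.
#' @param band numeric length-2 (Hz).
#' @return scalar `P_L`.
#' @export
low_freq_power <- function(estimate, band = c(1, 4)) {
  sel <- estimate$freq >= band[1] & estimate$freq <= band[2]
  if (!any(sel)) stop("band outside the frequency grid")
  mean(estimate$S_norm[sel])
}

#' Fano-factor timecourse with spontaneous and evoked summaries
#'
#' Computes `FF = var(n_sp) / mean(n_sp)` across trials for every cell and
#' sliding window, the spontaneous FF (window ending at stimulus onset),
#' the evoked FF at the time of the minimum of the population-averaged
#' timecourse within `evoked_limit` after onset, and their difference.
#'
#' @param counts output of [sliding_counts()] (times relative to onset).
#' @param evoked_limit scan limit for the evoked minimum (s after onset).
#' @return list with `FF` (cells x windows), `centers`, `FF_spont`,
#'   `FF_evoked`, `delta_FF` (per cell), `t_FFmin_index`, and the
#'   population means `FF_spont_mean`, `FF_evoked_mean`, `delta_FF_mean`.
#' @export
fano_timecourse <- function(counts, evoked_limit = 0.2) {
  x <- counts$counts
  if (dim(x)[2] < 2) stop("need >= 2 trials")
  mu <- apply(x, c(1, 3), mean)
  v <- apply(x, c(1, 3), stats::var)
  FF <- ifelse(mu > 0, v / mu, NA_real_)
  starts <- counts$starts
  ends <- starts + counts$window
  # spontaneous: the window immediately preceding onset (end closest to 0
  # from below, i.e. fully inside the pre-stimulus period)
  sp_idx <- which(ends <= 1e-9)
  if (!length(sp_idx)) stop("no fully pre-onset window")
  sp_idx <- sp_idx[length(sp_idx)]
  # evoked scan: windows starting after onset, up to evoked_limit
  ev_idx <- which(starts > -1e-9 & ends <= evoked_limit + 1e-9)
  pop <- colMeans(FF, na.rm = TRUE)
  t_min <- if (length(ev_idx)) ev_idx[which.min(pop[ev_idx])] else NA_integer_
  FF_spont <- FF[, sp_idx]
  FF_evoked <- if (is.na(t_min)) rep(NA_real_, nrow(FF)) else FF[, t_min]
  list(FF = FF, centers = counts$centers,
       FF_spont = FF_spont, FF_evoked = FF_evoked,
       delta_FF = FF_spont - FF_evoked,
       t_FFmin_index = t_min,
       FF_spont_mean = mean(FF_spont, na.rm = TRUE),
       FF_evoked_mean = mean(FF_evoked, na.rm = TRUE),
       delta_FF_mean = mean(FF_spont - FF_evoked, na.rm = TRUE))
}
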