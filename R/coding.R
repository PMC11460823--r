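# Population decoding and single-cell discriminability.
#
# The decoder is a multiclass linear discriminant with a shared within-class
# covariance (equal priors on balanced data), evaluated with repeated
# stratified cross-validation on sliding-window spike counts. Shuffle nulls
# permute stimulus labels. Single-cell discriminability follows the classic
# d-prime with a pooled standard deviation.

#' Sliding-window spike counts
#'
#' Counts spikes of every unit in overlapping windows stepped along each
#' trial, relative to stimulus onset.
#'
#' @param spikes `data.table` with columns `unit`, `time`, `trial`; times
#'   are relative to stimulus onset (use `time - t_stim` upstream).
#' @param trials integer vector of trial ids to include (defines the trial
#'   axis ordering).
#' @param units integer vector of unit ids (defines the unit axis).
#' @param window window length (s).
#' @param step window increment (s).
#' @param span numeric length-2: trial span relative to onset.
#' @return list with `counts` (units x trials x windows array), `centers`
#'   (window centers, s), `starts`, `window`, `step`.
#' @export
sliding_counts <- function(spikes, trials, units, window = 0.1,
                           step = 0.02, span = c(-0.1, 0.6)) {
  if (diff(span) < window) stop("span shorter than window")
  starts <- seq(span[1], span[2] - window + 1e-12, by = step)
  nw <- length(starts)
  nu <- length(units); ntr <- length(trials)
  counts <- array(0L, dim = c(nu, ntr, nw))
  uidx <- match(spikes$unit, units)
  tidx <- match(spikes$trial, trials)
  keep <- !is.na(uidx) & !is.na(tidx)
  uidx <- uidx[keep]; tidx <- tidx[keep]; tt <- spikes$time[keep]
  # each spike falls in at most ceiling(window / step) overlapping windows
  k_over <- ceiling(window / step)
  w0 <- floor((tt - span[1]) / step) + 1L
  for (j in 0:(k_over - 1L)) {
    w <- w0 - j
    ok <- w >= 1L & w <= nw
    ok[ok] <- tt[ok] >= starts[w[ok]] & tt[ok] < starts[w[ok]] + window
    if (!any(ok)) next
    flat <- (w[ok] - 1L) * (nu * ntr) + (tidx[ok] - 1L) * nu + uidx[ok]
    tb <- tabulate(flat, nbins = nu * ntr * nw)
    counts <- counts + array(tb, dim = c(nu, ntr, nw))
  }
  list(counts = counts, centers = starts + window / 2, starts = starts,
       window = window, step = step)
}

# --- multiclass LDA with shared, spectrally-regularized covariance -------

.lda_fit <- function(X, y, reg = 1e-4) {
  classes <- sort(unique(y))
  d <- ncol(X)
  mus <- t(vapply(classes, function(c) colMeans(X[y == c, , drop = FALSE]),
                  numeric(d)))
  Sw <- matrix(0, d, d)
  for (c in classes) {
    Xi <- X[y == c, , drop = FALSE]
    Xi <- sweep(Xi, 2, colMeans(Xi))
    Sw <- Sw + crossprod(Xi)
  }
  Sw <- Sw / max(nrow(X) - length(classes), 1L)
  Sw <- Sw + diag(reg * max(mean(diag(Sw)), 1e-12), d)
  R <- chol(Sw)
  A <- backsolve(R, backsolve(R, t(mus), transpose = TRUE))  # Sw^-1 mus'
  b <- -0.5 * colSums(t(mus) * A)
  list(classes = classes, A = A, b = b)
}

.lda_predict <- function(fit, X) {
  scores <- X %*% fit$A + rep(fit$b, each = nrow(X))
  fit$classes[max.col(scores, ties.method = "first")]
}

# stratified fold assignment: per class, shuffled round-robin
.stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (c in unique(y)) {
    idx <- which(y == c)
    fold[idx[sample.int(length(idx))]] <-
      rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validated decoding accuracy as a function of time
#'
#' For each sliding window, repeated stratified k-fold cross-validation of
#' a multiclass linear discriminant classifier with shared covariance;
#' accuracy is the mean fraction of correctly classified held-out trials
#' over all train/test splits. The summary `peak_accuracy` is the maximum
#' of the accuracy timecourse (earliest window on ties).
#'
#' @param counts output of [sliding_counts()] (or a compatible list).
#' @param labels stimulus label per trial (must be balanced; subsample with
#'   [balance_labels()] first if needed).
#' @param n_folds folds per repetition.
#' @param n_repeats repetitions of the cross-validation.
#' @param reg spectral regularization factor of the pooled covariance.
#' @param seed RNG seed controlling fold assignment.
#' @return An object of class `decoding_result`: `accuracy` per window,
#'   `centers`, `peak_accuracy`, `peak_window` (index), `n_folds`,
#'   `n_repeats`.
#' @export
decode_timecourse <- function(counts, labels, n_folds = 5, n_repeats = 10,
                              reg = 1e-4, seed = 1) {
  labels <- as.vector(labels)
  if (length(unique(table(labels))) != 1L)
    stop("labels must be balanced across classes")
  if (min(table(labels)) < n_folds)
    stop("fewer trials per class than folds")
  set.seed(seed)
  nw <- dim(counts$counts)[3]
  acc <- numeric(nw)
  folds <- replicate(n_repeats, .stratified_folds(labels, n_folds))
  for (w in seq_len(nw)) {
    X <- t(counts$counts[, , w])
    correct <- total <- 0
    for (r in seq_len(n_repeats)) {
      for (k in seq_len(n_folds)) {
        te <- folds[, r] == k
        fit <- .lda_fit(X[!te, , drop = FALSE], labels[!te], reg)
        pred <- .lda_predict(fit, X[te, , drop = FALSE])
        correct <- correct + sum(pred == labels[te])
        total <- total + sum(te)
      }
    }
    acc[w] <- correct / total
  }
  pk <- which.max(acc)  # which.max returns the earliest maximum
  structure(list(accuracy = acc, centers = counts$centers,
                 peak_accuracy = acc[pk], peak_window = pk,
                 n_folds = n_folds, n_repeats = n_repeats),
            class = "decoding_result")
}

#' Subsample trials so every label has equally many
#'
#' @param labels label per trial.
#' @param seed RNG seed.
#' @return integer indices of the retained trials.
#' @export
balance_labels <- function(labels, seed = 1) {
  set.seed(seed)
  n_min <- min(table(labels))
  sort(unlist(lapply(split(seq_along(labels), labels), function(idx)
    idx[sample.int(length(idx), n_min)])))
}

#' Label-shuffle null distribution of decoding accuracy
#'
#' Each shuffle permutes the stimulus labels across trials, draws one
#' stratified train/test split (default 80/20), trains the classifier and
#' records test accuracy per window.
#'
#' @inheritParams decode_timecourse
#' @param n_shuffles number of label shufflings.
#' @param test_frac held-out fraction.
#' @return list with `null` (shuffles x windows matrix), `q95` per window,
#'   and `centers`.
#' @export
shuffle_null <- function(counts, labels, n_shuffles = 100, test_frac = 0.2,
                         reg = 1e-4, seed = 1) {
  set.seed(seed)
  labels <- as.vector(labels)
  nw <- dim(counts$counts)[3]
  null <- matrix(NA_real_, n_shuffles, nw)
  if (n_shuffles == 0)
    return(list(null = null, q95 = rep(NA_real_, nw),
                centers = counts$centers))
  k <- max(2L, round(1 / test_frac))
  for (s in seq_len(n_shuffles)) {
    lab <- sample(labels)
    fold <- .stratified_folds(lab, k)
    te <- fold == 1L
    for (w in seq_len(nw)) {
      X <- t(counts$counts[, , w])
      fit <- .lda_fit(X[!te, , drop = FALSE], lab[!te], reg)
      pred <- .lda_predict(fit, X[te, , drop = FALSE])
      null[s, w] <- mean(pred == lab[te])
    }
  }
  list(null = null,
       q95 = apply(null, 2, stats::quantile, probs = 0.95, names = FALSE),
       centers = counts$centers)
}

#' Decoding with repeated random cell subsamples (one cell per cluster)
#'
#' Mirrors the feature-selection scheme used for the circuit models: in a
#' clustered network, one E cell is drawn from each cluster plus one from
#' the background (p + 1 features); in a uniform network, p + 1 E cells are
#' drawn at random. Decoding is repeated over `n_runs` independent samples
#' and the accuracy timecourses averaged.
#'
#' @param trialset a `trial_set` from [run_experiment()].
#' @param n_runs number of cell subsamples.
#' @param window,step,span sliding-window parameters (model convention:
#'   100 ms windows, 20 ms steps, span `[-0.1, 0.6]` s).
#' @param n_folds,n_repeats,reg passed to [decode_timecourse()].
#' @param seed RNG seed.
#' @return A `decoding_result` with the run-averaged accuracy, plus
#'   `per_run_peak` (peak accuracy of each run).
#' @export
model_feature_sample <- function(trialset, n_runs = 25, window = 0.1,
                                 step = 0.02, span = c(-0.1, 0.6),
                                 n_folds = 5, n_repeats = 10, reg = 1e-4,
                                 seed = 1) {
  inst <- trialset$instance
  p <- inst$arch$p
  evoked <- which(!is.na(trialset$trial_stim))
  labels <- trialset$trial_stim[evoked]
  sp <- data.table::copy(trialset$spikes[!is.na(trialset$spikes$stim)])
  sp[, time := time - trialset$t_stim]
  unitsE <- which(inst$pop == "E")
  counts_all <- sliding_counts(sp, trials = evoked, units = unitsE,
                               window = window, step = step, span = span)
  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max / 2, n_runs)
  accs <- NULL
  peaks <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    set.seed(run_seeds[r])
    if (inst$kind == "clustered") {
      feat <- vapply(seq_len(p + 1L), function(g)
        .draw(which(inst$cluster_of[unitsE] == g), 1L), integer(1))
    } else {
      feat <- .draw(seq_along(unitsE), p + 1L)
    }
    sub <- list(counts = counts_all$counts[feat, , , drop = FALSE],
                centers = counts_all$centers)
    dec <- decode_timecourse(sub, labels, n_folds, n_repeats, reg,
                             seed = run_seeds[r])
    accs <- if (is.null(accs)) dec$accuracy else accs + dec$accuracy
    peaks[r] <- dec$peak_accuracy
  }
  acc <- accs / n_runs
  pk <- which.max(acc)
  structure(list(accuracy = acc, centers = counts_all$centers,
                 peak_accuracy = acc[pk], peak_window = pk,
                 per_run_peak = peaks, n_runs = n_runs,
                 n_folds = n_folds, n_repeats = n_repeats),
            class = "decoding_result")
}

#' Single-cell discriminability (d-prime) pipeline
#'
#' For every cell, window and stimulus pair, computes
#' `d' = (mu_a - mu_b) / sqrt((sigma_a^2 + sigma_b^2) / 2)` from the
#' across-trial spike-count moments, averages `|pairs|` per cell (pairs with
#' zero pooled variance are dropped), then averages across cells to obtain a
#' population timecourse whose maximum defines the summary index `Dsc_prime`
#' and its window `t_star`; per-cell values are extracted at `t_star`.
#'
#' The pair average uses the magnitude of d-prime, making the summary
#' independent of the arbitrary orientation of each stimulus pair (the
#' shuffled-label floor of the summary is then the positive small-sample
#' bias of the magnitude).
#'
#' @param counts output of [sliding_counts()].
#' @param labels stimulus label per trial.
#' @return list with `timecourse`, `centers`, `Dsc_prime`, `t_star_index`,
#'   `per_cell` (at `t_star`), `per_cell_time` (cells x windows),
#'   `n_dropped` (pairs excluded for zero pooled SD).
#' @export
dprime_pipeline <- function(counts, labels) {
  labels <- as.vector(labels)
  stims <- sort(unique(labels))
  if (min(table(labels)) < 2) stop("need >= 2 trials per stimulus")
  nc <- dim(counts$counts)[1]
  nw <- dim(counts$counts)[3]
  pairs <- utils::combn(stims, 2)
  dbar <- matrix(NA_real_, nc, nw)
  n_dropped <- 0L
  for (w in seq_len(nw)) {
    X <- counts$counts[, , w, drop = FALSE][, , 1]
    if (nc == 1L) X <- matrix(X, nrow = 1L)
    mus <- vapply(stims, function(s) rowMeans(X[, labels == s, drop = FALSE]),
                  numeric(nc))
    vars <- vapply(stims, function(s) {
      Xi <- X[, labels == s, drop = FALSE]
      m <- rowMeans(Xi)
      (rowSums(Xi^2) - ncol(Xi) * m^2) / (ncol(Xi) - 1L)
    }, numeric(nc))
    vars[vars < 0] <- 0
    acc <- matrix(0, nc, 1); cnt <- matrix(0, nc, 1)
    for (k in seq_len(ncol(pairs))) {
      a <- match(pairs[1, k], stims); b <- match(pairs[2, k], stims)
      pooled <- sqrt((vars[, a] + vars[, b]) / 2)
      ok <- pooled > 0
      n_dropped <- n_dropped + sum(!ok)
      d <- abs(mus[, a] - mus[, b]) / pooled
      acc[ok] <- acc[ok] + d[ok]
      cnt[ok] <- cnt[ok] + 1
    }
    dbar[, w] <- ifelse(cnt > 0, acc / cnt, NA_real_)
  }
  tc <- colMeans(dbar, na.rm = TRUE)
  t_star <- which.max(tc)
  list(timecourse = tc, centers = counts$centers,
       Dsc_prime = tc[t_star], t_star_index = t_star,
       per_cell = dbar[, t_star], per_cell_time = dbar,
       n_dropped = n_dropped)
}

#' Normalize values within sessions and aggregate across conditions
#'
#' Implements the session-averaging convention: values (one per condition,
#' e.g. per pupil decile or per modulation strength) are z-scored within
#' each session/realization, assigned to non-overlapping condition bins,
#' duplicates within a session-bin averaged, and finally aggregated across
#' sessions (mean and SD per bin). Sessions with fewer than two conditions,
#' or zero variance across conditions, are excluded with a flag.
#'
#' @param df data.frame with columns `session`, `condition` (numeric, e.g.
#'   pupil % of max), `value`.
#' @param bin_breaks numeric vector of bin edges on the condition axis
#'   (default: width-10 bins over 0..100).
#' @return list with `bins` (data.frame: `mid`, `mean`, `sd`, `n`),
#'   `per_session` (normalized values with bin assignment), `excluded`
#'   (session ids).
#' @export
condition_normalize_and_bin <- function(df,
                                        bin_breaks = seq(0, 100, by = 10)) {
  excluded <- c()
  rows <- list()
  for (s in unique(df$session)) {
    d <- df[df$session == s, ]
    if (nrow(d) < 2 || stats::sd(d$value) == 0) {
      excluded <- c(excluded, s)
      next
    }
    z <- (d$value - mean(d$value)) / stats::sd(d$value)
    bin <- findInterval(d$condition, bin_breaks, rightmost.closed = TRUE)
    dt <- data.table::data.table(session = s, bin = bin, z = z)
    rows[[length(rows) + 1L]] <- dt[, .(z = mean(z)), by = .(session, bin)]
  }
  if (!length(rows)) stop("no usable sessions")
  allb <- data.table::rbindlist(rows)
  agg <- allb[, .(mean = mean(z), sd = stats::sd(z), n = .N), by = bin]
  data.table::setorder(agg, bin)
  mids <- (bin_breaks[-length(bin_breaks)] + bin_breaks[-1]) / 2
  agg[, mid := mids[bin]]
  list(bins = as.data.frame(agg[, .(mid, mean, sd, n)]),
       per_session = as.data.frame(allb), excluded = excluded)
}
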