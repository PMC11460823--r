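# Sliding counts, the linear-discriminant decoder (with an independent
# MASS::lda cross-check), shuffle nulls, discriminability, and
# session-normalized binning.

library(data.table)

# synthetic counts object: units x trials x windows
make_counts <- function(arr, window = 0.1, step = 0.02, span0 = -0.1) {
  nw <- dim(arr)[3]
  starts <- span0 + (seq_len(nw) - 1) * step
  list(counts = arr, centers = starts + window / 2, starts = starts,
       window = window, step = step)
}

# separable data: each stimulus drives its own unit
separable_counts <- function(n_per = 10, n_stim = 5, nw = 6, gap = 20) {
  n_tr <- n_per * n_stim
  arr <- array(rpois(n_stim * n_tr * nw, 1), dim = c(n_stim, n_tr, nw))
  labels <- rep(seq_len(n_stim), each = n_per)
  for (s in seq_len(n_stim))
    arr[s, labels == s, ] <- arr[s, labels == s, ] + gap
  list(counts = make_counts(arr), labels = labels)
}

test_that("sliding counts respect window overlap and conserve spikes", {
  spikes <- data.table(unit = c(1L, 1L, 2L),
                       time = c(0, 0.25, 0.13), trial = c(1L, 1L, 2L))
  cts <- sliding_counts(spikes, trials = 1:2, units = 1:2,
                        window = 0.1, step = 0.02, span = c(-0.1, 0.6))
  # a spike at t = 0 is counted in every window containing 0
  contain0 <- which(cts$starts <= 0 & cts$starts + 0.1 > 0)
  expect_true(all(cts$counts[1, 1, contain0] >= 1))
  expect_true(all(cts$counts[1, 1, setdiff(seq_along(cts$starts),
    which(cts$starts <= 0.25 & cts$starts + 0.1 > 0 |
            cts$starts <= 0 & cts$starts + 0.1 > 0))] == 0))
  # disjoint windows partition the span and recover the total count
  cts2 <- sliding_counts(spikes, trials = 1:2, units = 1:2,
                         window = 0.1, step = 0.1, span = c(-0.1, 0.6))
  expect_identical(sum(cts2$counts), 3L)
  expect_error(sliding_counts(spikes, 1:2, 1:2, window = 1,
                              span = c(0, 0.5)), "span")
  # empty input gives all-zero counts
  cts3 <- sliding_counts(spikes[0], trials = 1:2, units = 1:2)
  expect_true(all(cts3$counts == 0))
})

test_that("the decoder is perfect on separable data and at chance on shuffles", {
  set.seed(1)
  sep <- separable_counts()
  dec <- decode_timecourse(sep$counts, sep$labels, seed = 2)
  expect_equal(dec$peak_accuracy, 1)
  expect_true(all(dec$accuracy == 1))
  # label permutation: chance for 5 classes
  shuf_labels <- sample(sep$labels)
  dec0 <- decode_timecourse(sep$counts, shuf_labels, seed = 2)
  se <- sqrt(0.2 * 0.8 / (50 * 6))
  expect_lt(abs(mean(dec0$accuracy) - 0.2), 3 * se + 0.05)
  expect_error(decode_timecourse(sep$counts, rep(1:5, c(9, 11, 10, 10, 10))),
               "balanced")
})

test_that("decoding is invariant to unit reordering", {
  set.seed(5)
  sep <- separable_counts(gap = 3)
  dec <- decode_timecourse(sep$counts, sep$labels, seed = 3)
  perm <- sample(dim(sep$counts$counts)[1])
  cts_p <- make_counts(sep$counts$counts[perm, , ])
  dec_p <- decode_timecourse(cts_p, sep$labels, seed = 3)
  expect_equal(dec$accuracy, dec_p$accuracy)
})

test_that("the shared-covariance discriminant agrees with MASS::lda", {
  set.seed(11)
  n <- 60; d <- 4
  mu <- matrix(rnorm(3 * d, sd = 2), 3)
  y <- rep(1:3, each = n / 3)
  X <- mu[y, ] + matrix(rnorm(n * d), n)
  fit <- arousalnet:::.lda_fit(X, y, reg = 1e-10)
  pred <- arousalnet:::.lda_predict(fit, X)
  ref <- MASS::lda(X, grouping = factor(y))
  pred_ref <- as.integer(as.character(predict(ref, X)$class))
  expect_gt(mean(pred == pred_ref), 0.98)
})

test_that("the shuffle null brackets chance and flags informative data", {
  set.seed(9)
  sep <- separable_counts(n_per = 12, nw = 4)
  null <- shuffle_null(sep$counts, sep$labels, n_shuffles = 60, seed = 4)
  expect_lt(abs(mean(null$null) - 0.2), 0.05)
  dec <- decode_timecourse(sep$counts, sep$labels, seed = 5)
  expect_true(all(dec$accuracy > null$q95))
  empty <- shuffle_null(sep$counts, sep$labels, n_shuffles = 0)
  expect_true(all(is.na(empty$q95)))
})

test_that("d-prime follows the pooled-SD formula and excludes degenerate pairs", {
  # unit 1: mu = (2, 0), sd = 1 -> d' = 2 between stimuli 1 and 2
  set.seed(21)
  n_per <- 2000
  arr <- array(0, dim = c(2, 2 * n_per, 1))
  labels <- rep(1:2, each = n_per)
  arr[1, labels == 1, 1] <- rnorm(n_per, 2, 1)
  arr[1, labels == 2, 1] <- rnorm(n_per, 0, 1)
  arr[2, , 1] <- 5  # constant counts: zero pooled SD, dropped
  dp <- dprime_pipeline(make_counts(arr, step = 0.1), labels)
  expect_equal(unname(dp$per_cell[1]), 2, tolerance = 0.1)
  expect_true(is.na(dp$per_cell[2]))
  expect_gt(dp$n_dropped, 0)
  # identical distributions: d' ~ 0 (small-sample floor)
  arr2 <- array(rpois(2 * 2 * n_per, 5), dim = c(2, 2 * n_per, 1))
  dp2 <- dprime_pipeline(make_counts(arr2, step = 0.1), labels)
  expect_lt(dp2$Dsc_prime, 0.1)
})

test_that("shuffled labels push discriminability to its bias floor", {
  set.seed(31)
  sep <- separable_counts(n_per = 15, nw = 3, gap = 6)
  dp_info <- dprime_pipeline(sep$counts, sep$labels)
  dp_null <- dprime_pipeline(sep$counts, sample(sep$labels))
  expect_gt(dp_info$Dsc_prime, 3 * dp_null$Dsc_prime)
})

test_that("session normalization bins and aggregates as specified", {
  df <- data.frame(session = rep(c("a", "b"), each = 4),
                   condition = c(5, 15, 25, 35, 25, 35, 45, 55),
                   value = c(1, 2, 3, 4, 2, 4, 6, 8))
  out <- condition_normalize_and_bin(df)
  # sessions only contribute to bins they sampled
  expect_false(any(out$per_session$session == "b" & out$per_session$bin < 3))
  # shared bins average the two sessions' normalized values
  za <- scale(c(1, 2, 3, 4))[, 1]
  zb <- scale(c(2, 4, 6, 8))[, 1]
  bin3 <- out$bins[out$bins$mid == 25, ]
  expect_equal(bin3$mean, mean(c(za[3], zb[1])), tolerance = 1e-10)
  # zero-variance sessions are excluded
  df2 <- rbind(df, data.frame(session = "c", condition = c(10, 20),
                              value = c(1, 1)))
  out2 <- condition_normalize_and_bin(df2)
  expect_identical(out2$excluded, "c")
})

test_that("cluster-sampled decoding uses one cell per cluster plus background", {
  cfg <- default_config("reduced")
  arch <- cfg$arch
  inst <- build_clustered(arch, cfg$neuron, seed = 17)
  nu <- assign_external_rates(inst, arousal_modulation("mean"))
  stims <- make_stimulus_set(inst, t_stim = 0.3, seed = 2)
  ts <- run_experiment(inst, nu, stims,
                       sim_config(trial_duration = 1, t_stim = 0.3,
                                  n_trials_per_stimulus = 6, seed = 5))
  dec <- model_feature_sample(ts, n_runs = 2, span = c(-0.1, 0.4), seed = 3)
  expect_length(dec$per_run_peak, 2)
  expect_true(all(dec$accuracy >= 0 & dec$accuracy <= 1))
})
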