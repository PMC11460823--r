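# Synthetic sessions and the data-side preprocessing pipeline: pupil
# cleaning, amplitude QC, tone-responsiveness, decile partitions and
# rate-arousal classification.

test_that("session generation is reproducible and honors the protocol", {
  cf <- session_config(n_units = 8, n_blocks = 2, spont_block_s = 20,
                       evoked_block_s = 40)
  s1 <- generate_session(cf, seed = 3)
  s2 <- generate_session(cf, seed = 3)
  expect_identical(s1$spikes, s2$spikes)
  expect_identical(s1$pupil$diameter, s2$pupil$diameter)
  # tone schedule: 25 ms tones, 775 ms ISI -> 800 ms period within blocks
  d <- diff(s1$events$time)
  expect_true(all(abs(d - 0.8) < 1e-9 | d > 1))
  expect_true(all(s1$events$freq %in% c(2, 4, 8, 16, 32)))
  # events only inside evoked epochs; blocks alternate
  for (b in seq_len(nrow(s1$blocks))) {
    inb <- s1$events$time >= s1$blocks$start[b] &
      s1$events$time < s1$blocks$end[b]
    expect_true(all(s1$events$time[inb] >= s1$blocks$spont_end[b]))
  }
  expect_true(all(s1$pupil$diameter <= 100))
})

test_that("pupil cleaning masks sharp jumps and normalizes the trace", {
  n <- 20000
  raw <- 5 + sin(seq(0, 4 * pi, length.out = n))
  cleaned0 <- clean_pupil(raw)
  expect_true(all(cleaned0$valid))
  expect_equal(max(cleaned0$diameter, na.rm = TRUE), 100)
  # constant trace: unchanged up to normalization
  con <- clean_pupil(rep(4, n))
  expect_true(all(abs(con$diameter - 100) < 1e-9, na.rm = TRUE))
  # a normalized step of 0.2 masks [-250, +500] ms around the jump
  raw2 <- raw
  raw2[10000:n] <- raw2[10000:n] + 0.2 * max(raw)
  cleaned2 <- clean_pupil(raw2)
  expect_true(all(!cleaned2$valid[(10000 - 240):(10000 + 490)]))
  expect_true(cleaned2$valid[10000 - 300])
  expect_true(cleaned2$valid[10000 + 600])
  # a 0.05 step stays below the 0.08 threshold: nothing masked
  raw3 <- raw
  raw3[10000:n] <- raw3[10000:n] + 0.05 * max(raw)
  expect_true(all(clean_pupil(raw3)$valid))
})

test_that("unit QC keeps clean units and rejects injected defects", {
  set.seed(23)
  T_len <- 3600
  st <- rpois_train(5, T_len)
  amp_ok <- 12 * (1 + 0.05 * rnorm(length(st)))
  qc <- unit_qc(st, amp_ok, T_len)
  expect_true(qc$keep)
  # low rate
  qc_low <- unit_qc(rpois_train(0.1, T_len), rep(12, 360), T_len)
  expect_false(qc_low$keep)
  expect_true("low_rate" %in% qc_low$reasons)
  # bimodal amplitudes (50/50 mixture, ~60 percent separation) in a third
  # of the session
  amp_bad <- amp_ok
  mid <- st > T_len * 0.3 & st < T_len * 0.65
  flip <- mid & runif(length(st)) < 0.5
  amp_bad[flip] <- amp_bad[flip] * 0.45
  qc_bi <- unit_qc(st, amp_bad, T_len)
  expect_false(qc_bi$keep)
  expect_true("multimodal_amplitude" %in% qc_bi$reasons)
  # drift into the detection floor during the third quarter, then clipped
  u01 <- pmax((st - 0.5 * T_len) / (0.5 * T_len), 0)
  amp_dr <- pmax(amp_ok * pmax(1 - 2 * u01, 0), 1.2)
  qc_dr <- unit_qc(st, amp_dr, T_len)
  expect_false(qc_dr$keep)
  expect_true("noise_floor_drift" %in% qc_dr$reasons)
})

test_that("tone responsiveness detects onset responses and not silence", {
  set.seed(24)
  onsets <- seq(10, 100, by = 0.8)
  events <- data.frame(time = onsets,
                       freq = rep(c(2, 4), length.out = length(onsets)))
  # background 5 Hz; times 5 rate for 50 ms after each tone-2 onset
  st <- rpois_train(5, 105)
  extra <- unlist(lapply(onsets[events$freq == 2], function(o)
    o + sort(runif(rpois(1, 0.05 * 20), 0.005, 0.055))))
  st <- sort(c(st, extra))
  res <- tone_responsiveness(st, events)
  expect_true(res[["2"]])
  # a silent unit responds to nothing
  res0 <- tone_responsiveness(numeric(0), events)
  expect_false(any(res0))
})

test_that("stimulus-independent units rarely pass the responsiveness test", {
  set.seed(25)
  onsets <- seq(5, 60, by = 0.8)
  events <- data.frame(time = onsets, freq = rep(2, length(onsets)))
  hits <- vapply(1:10, function(k)
    tone_responsiveness(rpois_train(8, 65), events)[["2"]], logical(1))
  expect_lte(sum(hits), 2)
})

test_that("decile partitions are balanced and respect exclusions", {
  set.seed(26)
  pupil <- runif(1000)
  part <- pupil_decile_partition(pupil)
  expect_equal(as.integer(table(part$partition)), rep(100L, 10))
  expect_true(all(diff(part$decile_mean_pupil) > 0))
  expect_error(pupil_decile_partition(rep(1, 100)), "degenerate")
  # per-tone balancing
  labels <- sample(1:5, 1000, replace = TRUE)
  part2 <- pupil_decile_partition(pupil, labels = labels)
  for (d in 1:10) {
    tab <- table(labels[which(part2$partition == d)])
    expect_identical(length(unique(tab)), 1L)
  }
  # exclusions never enter a partition
  excl <- pupil > 0.9
  part3 <- pupil_decile_partition(pupil, exclude = excl)
  expect_true(all(is.na(part3$partition[excl])))
})

test_that("rate-arousal classification follows the Spearman rule", {
  cond <- 1:10
  rates <- rbind(cond * 2,            # perfectly increasing
                 rev(cond) * 1.5,     # perfectly decreasing
                 rep(5, 10))          # constant: undefined, class none
  out <- rate_arousal_classification(rates, cond)
  expect_identical(out$class, c("positive", "negative", "none"))
  expect_error(rate_arousal_classification(rates[, 1:2], cond[1:2]),
               "conditions")
})

test_that("model arousal modulations produce the expected sign structure", {
  # mean modulation: spontaneous rates increase in every cell;
  # heterogeneity modulation: mixed increases and decreases
  cfg <- default_config("reduced")
  inst <- build_clustered(cfg$arch, cfg$neuron, seed = 41)
  z <- arousal_z(inst, seed = 42)
  grid <- c(0, 0.1, 0.2, 0.3, 0.4)
  scfg <- sim_config(trial_duration = 4, t_stim = 3.9)
  rate_mat <- function(kind) {
    sapply(grid, function(g) {
      mod <- if (kind == "mean") arousal_modulation("mean", dM_E = g)
             else arousal_modulation("heterogeneity", dH_E = g)
      counts <- numeric(inst$n)
      for (k in 1:4) {
        sp <- simulate_trial(inst, assign_external_rates(inst, mod, z),
                             NULL, scfg, seed = 300 + k + round(1e3 * g))
        tb <- tabulate(sp$unit, nbins = inst$n)
        counts <- counts + tb
      }
      counts / 16
    })
  }
  rm_mean <- rate_mat("mean")
  cl_mean <- rate_arousal_classification(rm_mean, grid)
  fr_mean <- attr(cl_mean, "fractions")
  expect_gt(fr_mean["positive"], 0.1)
  expect_lt(fr_mean["negative"], 0.03)
  rm_het <- rate_mat("het")
  cl_het <- rate_arousal_classification(rm_het, grid)
  fr_het <- attr(cl_het, "fractions")
  expect_gt(fr_het["positive"], 0.05)
  expect_gt(fr_het["negative"], 0.05)
  expect_gt(fr_het["negative"], fr_mean["negative"])
})
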