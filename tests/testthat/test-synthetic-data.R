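# Synthetic session generator: determinism, degenerate configurations,
# label bookkeeping, count-model moments, behavioral calibration.

test_that("invalid configurations are rejected", {
  expect_error(generator_config(trial_duration = -1), "non-positive")
  expect_error(generator_config(trial_duration = 100, sample_epoch = c(0, 500)),
               "sample_epoch")
  expect_error(generator_config(touch_spike_prob = 1.3), "binomial")
  expect_error(generator_config(baseline_rate = -2), "non-negative")
  expect_silent(generator_config(touch_spike_prob = 1.3,
                                 count_model = "poisson"))
})

test_that("identical seeds give identical sessions", {
  cfg <- generator_config(n_trials = 4, seed = 77)
  s1 <- generate_session(cfg)
  s2 <- generate_session(cfg)
  expect_identical(s1$spikes, s2$spikes)
  expect_identical(s1$touches, s2$touches)
  expect_identical(s1$traces[[2]]$theta, s2$traces[[2]]$theta)
  s3 <- generate_session(generator_config(n_trials = 4, seed = 78))
  expect_false(identical(s1$spikes, s3$spikes))
})

test_that("zero trials give an empty but valid session", {
  s <- generate_session(generator_config(n_trials = 0, seed = 1))
  expect_equal(nrow(s$spikes), 0L)
  expect_length(s$traces, 0L)
})

test_that("no-touch configuration yields flat curvature and no touches", {
  cfg <- generator_config(n_trials = 3, seed = 5, touches_per_trial_mean = 0)
  s <- generate_session(cfg)
  expect_true(is.null(s$touches) || nrow(s$touches) == 0L)
  for (tr in s$traces) expect_true(all(tr$kappa == 0))
})

test_that("zero whisking amplitude gives a quiet whisker and no whisking epochs", {
  cfg <- generator_config(n_trials = 2, seed = 5, whisk_p2p_amp = 0)
  s <- generate_session(cfg)
  for (tr in s$traces) {
    ph <- decompose_whisking(tr)
    ep <- segment_epochs(tr, ph)
    expect_equal(nrow(ep$whisking), 0L)
    expect_equal(nrow(tr$touch_intervals), 0L)
    expect_lt(max(abs(ph$theta_band)), 1.25)
  }
})

test_that("ground-truth labels partition the generated spikes", {
  sk <- default_session()
  s <- sk$session
  expect_equal(nrow(s$ground_truth), nrow(s$spikes))
  expect_true(all(s$ground_truth$label %in% c("touch", "phase", "baseline")))
  expect_identical(s$ground_truth$time, s$spikes$time)
})

test_that("binomial touch responses match closed-form Bernoulli moments", {
  cfg <- generator_config(n_trials = 220, seed = 9, baseline_rate = 0,
                          phase_A = 0, phase_B = 0, lick_prob = 0)
  s <- generate_session(cfg)
  expect_gt(nrow(s$touches), 400)
  counts <- touch_spike_counts(s$spikes, s$touches, c(0, 30))
  expect_true(all(counts %in% c(0L, 1L)))  # binomial mode: 0/1 per touch
  expect_lt(abs(mean(counts) - 0.7), 3 * sqrt(0.21 / length(counts)) + 0.01)
  expect_lt(abs(mean((counts - mean(counts))^2) - 0.21), 0.05)
})

test_that("poisson count model gives Poisson trial counts when touch-independent", {
  cfg <- generator_config(n_trials = 150, seed = 13, baseline_rate = 3,
                          touch_spike_prob = 0, touch_spike_prob_later = 0,
                          phase_A = 0, phase_B = 0, refractory = 0,
                          count_model = "poisson")
  s <- generate_session(cfg)
  per_trial <- tabulate(s$spikes$trial_id, nbins = 150)
  lam <- 3 * cfg$trial_duration / 1000
  expect_lt(abs(mean(per_trial) - lam), 3 * sqrt(lam / 150))
  expect_lt(abs(fano_factor(per_trial) - 1), 0.25)
})

test_that("deterministic unit response: one spike per touch at onset + latency", {
  cfg <- generator_config(n_trials = 30, seed = 21, baseline_rate = 0,
                          phase_A = 0, phase_B = 0, touch_spike_prob = 1,
                          touch_spike_prob_later = 1, touch_jitter = 0,
                          lick_prob = 0)
  s <- generate_session(cfg)
  expect_equal(nrow(s$spikes), nrow(s$touches))
  expect_equal(sort(s$spikes$time), sort(s$touches$onset + 8))
})

test_that("negative latency is an invalid configuration", {
  cfg <- generator_config(n_trials = 1, seed = 1)
  cfg$touch_latency <- -4
  tr <- generate_whisker_trace(cfg, 1)
  ph <- decompose_whisking(tr)
  tf <- extract_touch_features(tr)
  expect_error(generate_spikes(tr, tf, ph, cfg), "negative latency")
})

test_that("generated behavior is calibrated to the target statistics", {
  sk <- cached_session("calib200", generator_config(n_trials = 200, seed = 101))
  s <- sk$session
  kin <- sk$kin
  lens <- unlist(lapply(kin, function(k) {
    cy <- k$phase$cycles
    cy <- cy[cy$p2p > 2.5 & cy$monotonic, ]
    cy$end - cy$start
  }))
  freq <- 1000 / lens
  expect_lt(abs(mean(freq) - 15.4) / 15.4, 0.10)
  touches_per_trial <- nrow(s$touches) / 200
  expect_lt(abs(touches_per_trial - 2.33) / 2.33, 0.15)
})

test_that("bootstrap intervals of session statistics cover the calibration targets", {
  sk <- cached_session("calib40", generator_config(n_trials = 40, seed = 101))
  s <- sk$session
  kin <- sk$kin
  bouts <- c(); amps <- c(); freqs <- c()
  for (k in kin) {
    w <- k$epochs$whisking
    cy <- k$phase$cycles
    cyw <- cy[cy$p2p > 2.5 & cy$monotonic, ]
    freqs <- c(freqs, 1000 / (cyw$end - cyw$start))
    if (nrow(w)) {
      bouts <- c(bouts, w[, 2] - w[, 1])
      for (j in seq_len(nrow(w))) {
        inb <- cyw$start >= w[j, 1] - 1 & cyw$end <= w[j, 2] + 80
        if (any(inb)) amps <- c(amps, max(cyw$p2p[inb]))
      }
    }
  }
  tpt <- vapply(seq_len(40), function(i) sum(s$touches$trial_id == i),
                numeric(1))
  boot_ci <- function(x) {
    set.seed(7)
    bm <- replicate(1000, mean(sample(x, replace = TRUE)))
    stats::quantile(bm, c(0.025, 0.975), names = FALSE)
  }
  covers <- function(x, target) {
    ci <- boot_ci(x)
    ci[1] <= target && target <= ci[2]
  }
  expect_true(covers(bouts, 261))
  expect_true(covers(amps, 15.7))
  expect_true(covers(freqs, 15.4))
  expect_true(covers(tpt, 2.33))
})

test_that("session summary falls inside the observed single-cell ranges", {
  sk <- default_session()
  s <- sk$session
  kin <- sk$kin
  first <- s$touches[s$touches$is_first, ]
  spk_first <- mean(touch_spike_counts(s$spikes, first, c(0, 50)))
  expect_gte(spk_first, 0.08); expect_lte(spk_first, 5.77)
  lat <- onset_latency(touch_aligned_psth(s$spikes, s$touches, "all_touch"))
  expect_gte(lat, 4); expect_lte(lat, 18)
  pt <- phase_tuning(s$spikes, kin)
  expect_gte(pt$modulation_depth, 0); expect_lte(pt$modulation_depth, 1)
})
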