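# Touch-aligned PSTHs, onset latency, cosine phase tuning, epoch rates.

test_that("PSTH puts a delta response in the right bin at the right rate", {
  onsets <- seq(100, 100 * 100, by = 100)
  touches <- touch_table(onsets)
  spikes <- data.frame(trial_id = 1L, time = onsets + 10)
  ps <- touch_aligned_psth(spikes, touches, "all_touch", bin_width = 1)
  expect_equal(ps$n_events, 100L)
  expect_equal(ps$rate[ps$mid == 10], 1000)
  expect_equal(sum(ps$rate[ps$mid != 10]), 0)
})

test_that("PSTH conserves spike mass and supports alignments", {
  sk <- default_session()
  s <- sk$session
  for (al in c("all_touch", "first_touch")) {
    ps <- touch_aligned_psth(s$spikes, s$touches, al, bin_width = 5,
                             window = c(-50, 50))
    n_window <- 0
    ev <- if (al == "first_touch") s$touches[s$touches$is_first, ] else s$touches
    for (i in seq_len(nrow(ev))) {
      st <- s$spikes$time[s$spikes$trial_id == ev$trial_id[i]] - ev$onset[i]
      n_window <- n_window + sum(st >= -50 & st < 50)
    }
    expect_equal(sum(ps$rate) * ps$bin_width * ps$n_events / 1000, n_window)
  }
  expect_error(touch_aligned_psth(s$spikes, s$touches[0, ], "all_touch"),
               "no alignment events")
})

test_that("a spikeless train gives an all-zero PSTH", {
  touches <- touch_table(c(100, 300))
  ps <- touch_aligned_psth(data.frame(trial_id = integer(0),
                                      time = numeric(0)), touches)
  expect_true(all(ps$rate == 0))
})

test_that("onset latency finds a step over a silent baseline", {
  onsets <- seq(200, 200 * 80, by = 200)
  touches <- touch_table(onsets)
  spikes <- data.frame(trial_id = 1L, time = onsets + 8.2)
  ps <- touch_aligned_psth(spikes, touches, "all_touch")
  expect_equal(onset_latency(ps), 8)
  flat <- touch_aligned_psth(data.frame(trial_id = integer(0),
                                        time = numeric(0)), touches)
  expect_true(is.na(onset_latency(flat)))
})

test_that("onset latency matches a brute-force threshold scan on noisy baselines", {
  set.seed(31)
  onsets <- seq(300, 300 * 120, by = 300)
  touches <- touch_table(onsets)
  # noisy baseline everywhere plus a dense burst 12 ms after each onset
  base <- runif(1200, 0, 300 * 120)
  hit <- rbinom(length(onsets), 1, 0.8) == 1
  burst <- onsets[hit] + 12 + runif(sum(hit), 0, 0.8)
  spikes <- data.frame(trial_id = 1L, time = sort(c(base, burst)))
  ps <- touch_aligned_psth(spikes, touches, "all_touch")
  # oracle: independent scan over the same histogram
  pre <- ps$rate[ps$mid >= -50 & ps$mid < 0]
  thr <- mean(pre) + 2 * sd(pre)
  post <- which(ps$mid >= 0 & ps$mid < 50)
  oracle <- NA_real_
  for (k in post) if (ps$rate[k] > thr && ps$count[k] >= 1) {
    oracle <- ps$mid[k]; break
  }
  expect_equal(onset_latency(ps), oracle)
  # the rule fires at the embedded step at +12 or at an earlier baseline
  # excursion past two standard deviations, never later
  expect_lte(oracle, 12)
})

test_that("cosine fit recovers exact cosine-generated bin rates", {
  mid <- seq(-pi, pi, length.out = 13)[-13] + pi / 12
  for (pars in list(c(2, 1, 0.7), c(0.5, 0, -2.1), c(0, 3, 1))) {
    rate <- pars[1] * (1 + cos(mid - pars[3])) + pars[2]
    fit <- whisktouch:::fit_cosine(mid, rate, w = rep(1, 12))
    expect_equal(fit$A, pars[1], tolerance = 1e-5)
    expect_equal(fit$B, pars[2], tolerance = 1e-5)
    if (pars[1] > 0)
      expect_lt(abs(((fit$pref - pars[3] + pi) %% (2 * pi)) - pi), 1e-4)
  }
})

test_that("phase tuning recovers sharp and absent modulation", {
  # all spikes at phase 0 (mid-cycle of the sawtooth fake phase)
  ph <- fake_phase(4000, cycle_len = 100)
  ep <- fake_epochs(ph)
  kin <- fake_kin(ph, ep)
  spikes <- data.frame(trial_id = 1L, time = seq(50, 3950, by = 100))
  pt <- phase_tuning(spikes, kin)
  expect_gt(pt$modulation_depth, 0.9)
  expect_lt(abs(pt$phase_pref), 0.3)
  # uniform spiking: depth near zero
  set.seed(4)
  spikes_u <- data.frame(trial_id = 1L, time = sort(runif(2000, 0, 4000)))
  pt_u <- phase_tuning(spikes_u, kin)
  expect_lt(pt_u$modulation_depth, 0.1)
  # occupancy normalization holds as an identity
  expect_equal(pt_u$bins$rate, pt_u$bins$count / pt_u$bins$occupancy)
  expect_equal(sum(pt_u$bins$occupancy), 4)  # 4 s of usable whisking
})

test_that("phase tuning recovers a generative depth of one and errors without whisking", {
  cfg <- generator_config(n_trials = 40, seed = 43, phase_A = 4, phase_B = 0,
                          baseline_rate = 0, touches_per_trial_mean = 0,
                          lick_prob = 0, refractory = 0)
  sk <- cached_session("phase_depth1", cfg)
  pt <- phase_tuning(sk$session$spikes, sk$kin)
  expect_gt(pt$modulation_depth, 0.9)
  expect_lt(abs(pt$phase_pref), 0.35)
  ph <- fake_phase(1000)
  ep <- fake_epochs(ph)
  ep$cycles$phase_ok <- FALSE
  expect_error(phase_tuning(data.frame(trial_id = 1L, time = 500),
                            fake_kin(ph, ep)), "no usable whisking")
})

test_that("modulation depth is always inside [0, 1]", {
  ph <- fake_phase(3000)
  kin <- fake_kin(ph, fake_epochs(ph))
  set.seed(8)
  for (i in 1:5) {
    spikes <- data.frame(trial_id = 1L,
                         time = sort(runif(rpois(1, 40), 0, 3000)))
    if (nrow(spikes) == 0) next
    pt <- phase_tuning(spikes, kin)
    expect_gte(pt$modulation_depth, 0)
    expect_lte(pt$modulation_depth, 1)
  }
})

test_that("epoch rates, minimum ISI and per-touch counts are exact", {
  ph <- fake_phase(12000)
  ep <- fake_epochs(ph)
  ep$whisking <- cbind(0, 2000)
  ep$non_whisking <- cbind(2000, 12000)  # 10 s quiet
  kin <- fake_kin(ph, ep)
  spikes <- data.frame(trial_id = 1L, time = c(100, 102.9, 200, 3000, 4000,
                                               5000, 6000, 7000))
  er <- epoch_rates(spikes, kin)
  expect_equal(er$non_whisking_rate, 5 / 10)
  expect_equal(er$whisking_rate, 3 / 2)
  expect_equal(er$min_isi, 2.9)
  empty <- epoch_rates(data.frame(trial_id = integer(0), time = numeric(0)),
                       kin)
  expect_equal(empty$whisking_rate, 0)
  expect_true(is.na(empty$min_isi))
})
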