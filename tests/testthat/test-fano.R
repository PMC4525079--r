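# Fano factors, the binomial minimum, ICI selection, OPTICS grouping,
# sliding-window curves, refractory-Poisson nulls, alignment conditions.

test_that("fano_factor handles degenerate and textbook cases", {
  expect_equal(fano_factor(rep(1L, 10)), 0)
  expect_equal(fano_factor(c(rep(0L, 50), rep(1L, 50))), 0.5)
  set.seed(1)
  expect_lt(abs(fano_factor(rpois(1e5, 2)) - 1), 0.02)
  expect_warning(ff <- fano_factor(c(0L, 0L)), "mean count is zero")
  expect_true(is.na(ff))
  expect_error(fano_factor(1L), "at least 2")
  x <- c(0L, 1L, 1L, 2L)
  expect_equal(fano_factor(x, "sample") / fano_factor(x, "population"),
               4 / 3)
})

test_that("min_fano closed form matches exhaustive minimization", {
  expect_equal(min_fano(0.5), 0.5)
  expect_equal(min_fano(1), 0)
  expect_equal(min_fano(1.5), 1 / 6)
  expect_error(min_fano(-0.1), "non-negative")
  b <- min_fano_brute(0.5)
  expect_equal(b$ff, 0.5, tolerance = 1e-12)
  expect_equal(b$support, c(0, 1))
  expect_equal(b$prob, c(0.5, 0.5))
  for (mu in seq(0.05, 3, by = 0.05))
    expect_lt(abs(min_fano_brute(mu)$ff - min_fano(mu)), 1e-9)
})

test_that("empirical Fano factor never beats the binomial bound", {
  set.seed(2)
  for (i in 1:40) {
    x <- switch(1 + i %% 3,
                rpois(50, runif(1, 0.2, 3)),
                rbinom(50, 1, runif(1)),
                rbinom(50, 4, runif(1)))
    if (mean(x) == 0) next
    expect_gte(fano_factor(x), min_fano(mean(x)) - 1e-12)
  }
})

test_that("ICI selection is strict and keeps first touches", {
  tt <- data.frame(ici = c(Inf, 300, 100, 250), onset = 1:4)
  sel <- select_touches(tt)
  expect_equal(sel$onset, c(1, 2))
})

test_that("OPTICS orders well-separated clusters contiguously", {
  set.seed(3)
  x <- rbind(matrix(rnorm(60, 0, 0.3), ncol = 2),
             matrix(rnorm(60, 6, 0.3), ncol = 2))
  op <- optics_order(x, min_pts = 5)
  lab <- rep(1:2, each = 30)[op$order]
  expect_equal(sum(diff(lab) != 0), 1L)  # one transition between clusters
  expect_error(optics_order(x[1:3, ], min_pts = 5), "fewer points")
})

test_that("touch grouping recovers planted clusters and degrades gracefully", {
  set.seed(4)
  x <- rbind(matrix(rnorm(60, 0, 0.2), ncol = 2),
             matrix(rnorm(60, 5, 0.2), ncol = 2))
  grp <- group_touches(x, n_groups = 2, min_size = 30, frac = 0.5,
                       min_pts = 5)
  g1 <- sort(grp$groups[[1]])
  expect_true(identical(g1, 1:30) || identical(g1, 31:60))
  expect_equal(sort(unlist(grp$groups)), 1:60)
  # identical features: zero within-group spread
  same <- matrix(1, nrow = 120, ncol = 2)
  grp2 <- group_touches(same, n_groups = 5, min_size = 20, min_pts = 5)
  expect_true(all(grp2$group_sd == 0))
  expect_error(group_touches(x[1:20, ], n_groups = 5, min_size = 20),
               "at least")
})

test_that("grouped touches are less variable than random subsamples", {
  set.seed(5)
  n <- 400
  x <- cbind(rnorm(n), rnorm(n))
  x[, 2] <- 0.6 * x[, 1] + 0.8 * x[, 2]  # correlated features
  grp <- group_touches(x)
  rand_sd <- replicate(200, {
    ii <- sample.int(n, length(grp$groups[[1]]))
    mean(apply(grp$features_z[ii, ], 2, sd))
  })
  expect_lt(grp$group_sd[1], stats::quantile(rand_sd, 0.05))
  expect_lt(mean(grp$group_sd), mean(rand_sd))
})

test_that("sliding Fano factor is zero for deterministic responses", {
  onsets <- seq(100, 100 * 60, by = 100)
  touches <- touch_table(onsets)
  spikes <- data.frame(trial_id = 1L, time = onsets + 8)
  sf <- sliding_fano(spikes, touches, window = 10, offsets = 0:20,
                     n_boot = 50, seed = 1)
  row8 <- sf$curve[sf$curve$offset == 8, ]
  expect_equal(row8$ff, 0)
  expect_equal(row8$mean_count, 1)
  expect_equal(sf$min_ff_overall, 0)
})

test_that("binomial responses reach the binomial floor; Poisson responses stay at 1", {
  sk <- default_session()
  s <- sk$session
  sel <- select_touches(s$touches)
  sf <- sliding_fano(s$spikes, sel, n_boot = 100, seed = 2)
  expect_lt(abs(sf$min_ff[["0"]] - 0.3), 0.1)
  pooled <- sf$curve[sf$curve$group == 0, ]
  at_peak <- pooled[which.min(pooled$ff), ]
  expect_lt(abs(at_peak$binomial_min - min_fano(at_peak$mean_count)), 1e-12)
  # poisson count model: FF stays near 1 at response offsets
  cfgp <- generator_config(n_trials = 200, seed = 14, count_model = "poisson",
                           touch_spike_prob = 1.2, touch_spike_prob_later = 1.2,
                           baseline_rate = 0, phase_A = 0, phase_B = 0,
                           refractory = 0, lick_prob = 0)
  sp <- cached_session("poisson_touch", cfgp)
  sfp <- sliding_fano(sp$session$spikes, sp$session$touches, n_boot = 50,
                      seed = 3)
  resp <- sfp$curve[sfp$curve$group == 0 & sfp$curve$offset %in% 6:10, ]
  expect_lt(abs(mean(resp$ff) - 1), 0.12)
})

test_that("refractory Poisson null reproduces the Poisson and binomial limits", {
  flat <- structure(list(edges = seq(-50, 50), mid = seq(-50, 49),
                         count = rep(1, 100), rate = rep(50, 100),
                         n_events = 1, bin_width = 1,
                         alignment = "all_touch"), class = "psth")
  null0 <- refractory_poisson_null(flat, refractory = 0, n_events = 5000,
                                   seed = 4, n_boot = 50)
  expect_true(all(abs(null0$curve$ff - 1) < 0.06))
  # refractory much longer than the window: counts are 0/1, FF at the floor
  hot <- flat; hot$rate <- rep(200, 100)
  null_r <- refractory_poisson_null(hot, refractory = 50, n_events = 4000,
                                    seed = 5, n_boot = 50)
  expect_lt(max(abs(null_r$curve$ff - null_r$curve$binomial_min)), 0.05)
  silent <- flat; silent$rate <- rep(0, 100)
  null_s <- refractory_poisson_null(silent, refractory = 0, n_events = 100,
                                    seed = 6, n_boot = 20)
  expect_true(all(is.na(null_s$curve$ff)))
})

test_that("alignment conditions collapse for homogeneous Poisson spiking", {
  cfg <- generator_config(n_trials = 200, seed = 15, touch_spike_prob = 0,
                          touch_spike_prob_later = 0, phase_A = 0,
                          phase_B = 0, baseline_rate = 3, refractory = 0,
                          lick_prob = 0)
  sk <- cached_session("hom_poisson", cfg)
  ffs <- ff_conditions(sk$session, sk$kin, seed = 7)$ff
  expect_true(all(abs(ffs[1:3] - 1) < 0.15))
  # minima over offsets are downward-biased estimates of 1
  expect_true(all(ffs[4:5] > 0.6 & ffs[4:5] < 1.15))
})

test_that("a zero-variance responder gives zero FF in touch-aligned conditions", {
  cfg <- generator_config(n_trials = 120, seed = 16, touch_spike_prob = 1,
                          touch_spike_prob_later = 1, touch_jitter = 0,
                          baseline_rate = 0, phase_A = 0, phase_B = 0,
                          lick_prob = 0)
  sk <- cached_session("det_responder", cfg)
  ffs <- ff_conditions(sk$session, sk$kin, seed = 8)$ff
  expect_equal(unname(ffs[3:5]), c(0, 0, 0))
  expect_gt(ffs[1], 0)
})
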