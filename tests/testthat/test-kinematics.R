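# Whisking decomposition, epoch segmentation, touch features, reaction
# time.  Boundary thresholds are checked bit-exactly on hand-built phase
# objects so no filter artifacts blur them.

test_that("a pure in-band tone decomposes into the expected phase and envelope", {
  t <- 0:1999
  theta <- 10 * sin(2 * pi * 15 * t / 1000)
  tr <- whisker_trace(1L, theta)
  ph <- decompose_whisking(tr)
  interior <- 300:1700
  expect_lt(max(abs(ph$amplitude[interior] - 10)) / 10, 0.05)
  # phase advances 2*pi per cycle: cycle length 1000/15 = 66.7 ms
  cyc <- ph$cycles
  expect_gt(nrow(cyc), 20)
  expect_lt(max(abs((cyc$end - cyc$start) - 1000 / 15)), 1.6)
  # envelope * cos(phase) reconstructs the bandpassed signal
  err <- ph$theta_band[interior] - ph$amplitude[interior] * cos(ph$phi[interior])
  expect_lt(sqrt(mean(err^2)), 0.05)
})

test_that("degenerate traces are rejected or give empty decompositions", {
  expect_error(decompose_whisking(whisker_trace(1L, rep(0, 100))), "short")
  expect_error(decompose_whisking(whisker_trace(1L, rep(NA_real_, 500))), "NA")
  ph <- decompose_whisking(whisker_trace(1L, rep(3, 1000)))
  expect_lt(max(ph$amplitude[200:800]), 0.05)
  expect_equal(sum(ph$cycles$p2p > 2.5), 0L)
})

test_that("bandpassing an already band-limited signal is nearly a no-op", {
  t <- 0:2999
  x <- 4 * sin(2 * pi * 10 * t / 1000) + 2 * sin(2 * pi * 22 * t / 1000 + 1) +
    sin(2 * pi * 40 * t / 1000 + 2)
  ph <- decompose_whisking(whisker_trace(1L, x))
  interior <- 400:2600
  rel <- sqrt(mean((ph$theta_band[interior] - x[interior])^2)) /
    sqrt(mean(x[interior]^2))
  expect_lt(rel, 0.01)
})

test_that("cycle boundaries agree with a peak-finding oracle on noiseless bouts", {
  t <- 0:2499
  env <- ifelse(t >= 300 & t < 900, 1, ifelse(t >= 1500 & t < 2100, 1, 0))
  x <- 8 * env * cos(2 * pi * 15 * t / 1000)
  ph <- decompose_whisking(whisker_trace(1L, x))
  cyc <- ph$cycles[ph$cycles$p2p > 2.5, ]
  # oracle: retraction minima of the raw signal (cycle starts at -pi)
  mins <- which(diff(sign(diff(x))) > 0) # local minima indices (1-based of t+1)
  min_t <- t[mins + 1]
  min_t <- min_t[abs(x[mins + 1]) > 2]   # only real oscillation troughs
  for (st in cyc$start[cyc$start > 330 & cyc$start < 870])
    expect_lte(min(abs(min_t - st)), 2)
})

test_that("whisking and quiet epochs follow the amplitude and duration rules", {
  # bout of 300 ms at 5 deg p2p, the rest silent
  t <- 0:1499
  x <- ifelse(t >= 600 & t < 900, 2.5 * cos(2 * pi * 15 * t / 1000), 0)
  tr <- whisker_trace(1L, x)
  ph <- decompose_whisking(tr)
  ep <- segment_epochs(tr, ph)
  expect_gte(nrow(ep$whisking), 1L)
  expect_true(all(ep$whisking[, 1] >= 550 & ep$whisking[, 2] <= 950))
  # quiet flanks are long enough to count as non-whisking
  expect_gte(iv_total <- sum(ep$non_whisking[, 2] - ep$non_whisking[, 1]), 1000)
})

test_that("epoch thresholds are exact on hand-built phase objects", {
  n <- 1000
  ph <- fake_phase(n, cycle_len = 100, amp = 5)
  tr <- whisker_trace(1L, rep(0, n))
  # p2p exactly 2.5 does not qualify; strictly above does
  ph$cycles$p2p <- rep(c(2.5, 2.5 + 1e-9), length.out = nrow(ph$cycles))
  ep <- segment_epochs(tr, ph)
  expect_equal(ep$cycles$whisking, rep(c(FALSE, TRUE), length.out = 10))
  # quiet run of exactly 100 ms qualifies, 99 ms does not
  amp <- rep(2, n)
  amp[101:200] <- 1.2     # 100 ms below 1.25
  amp[401:499] <- 1.2     # 99 ms below 1.25
  ph2 <- fake_phase(n)
  ph2$amplitude <- amp
  ph2$cycles <- ph2$cycles[0, ]
  ep2 <- segment_epochs(tr, ph2)
  expect_equal(nrow(ep2$non_whisking), 1L)
  expect_equal(unname(ep2$non_whisking[1, ]), c(100, 200))
})

test_that("cycles in the touch shadow or during licking are unusable for phase", {
  n <- 1200
  ph <- fake_phase(n, cycle_len = 100, amp = 5)
  # touch at [305, 315): shadow covers [305, 385)
  tr <- whisker_trace(1L, rep(0, n), lick_times = 950,
                      touch_intervals = cbind(305, 315))
  ep <- segment_epochs(tr, ph)
  cyc <- ep$cycles
  expect_false(cyc$phase_ok[cyc$start == 300])  # overlaps the shadow
  expect_true(cyc$phase_ok[cyc$start == 400])   # starts after shadow end 385
  expect_false(cyc$phase_ok[cyc$start == 900])  # lick at 950
  expect_true(cyc$phase_ok[cyc$start == 100])
})

test_that("prolonged touches are dropped from exploration", {
  n <- 1000
  ph <- fake_phase(n, cycle_len = 100, amp = 0.5)  # no whisking (p2p 1 < 2.5)
  ph$cycles$p2p <- 1
  tr <- whisker_trace(1L, rep(0, n), pole_in_reach = c(0, 1000),
                      touch_intervals = rbind(c(100, 180), c(300, 450)))
  ep <- segment_epochs(tr, ph)
  expect_equal(nrow(ep$exploration), 1L)
  expect_equal(unname(ep$exploration[1, ]), c(100, 180))
})

test_that("touch features recover constructed velocity, curvature and ICI", {
  t <- 0:999
  theta <- pmin(t, 300) * 1.0          # 1 deg/ms up to t = 300
  kappa <- rep(0, 1000)
  kappa[t >= 100 & t < 112] <- 0.004 * (t[t >= 100 & t < 112] - 100) / 12
  kappa[t >= 112 & t < 150] <- 0.004
  tr <- whisker_trace(1L, theta, kappa,
                      touch_intervals = rbind(c(100, 150), c(400, 430)))
  tf <- extract_touch_features(tr)
  expect_equal(tf$pretouch_velocity[1], 1.0, tolerance = 1e-9)
  expect_equal(tf$max_dkappa[1], 0.004, tolerance = 1e-9)
  expect_equal(tf$ici, c(Inf, 250))
  expect_equal(nrow(select_touches(tf, 250)), 1L)  # 250 fails the strict rule
  expect_equal(tf$order, c(1L, 2L))
})

test_that("a touch at the trial start has undefined pretouch velocity", {
  tr <- whisker_trace(1L, rep(1, 500), touch_intervals = cbind(0, 40))
  tf <- extract_touch_features(tr)
  expect_true(is.na(tf$pretouch_velocity[1]))
})

test_that("reaction time subtracts first touch from first lick", {
  tr <- whisker_trace(1L, rep(0, 1000), lick_times = 867,
                      touch_intervals = cbind(500, 530))
  expect_equal(reaction_time(tr), 367)
  expect_true(is.na(reaction_time(whisker_trace(1L, rep(0, 500)))))
  tr2 <- whisker_trace(1L, rep(0, 1000), lick_times = 400,
                       touch_intervals = cbind(500, 530))
  rt <- reaction_time(tr2)
  expect_equal(as.numeric(rt), 400 - 500)
  expect_true(isTRUE(attr(rt, "premature")))
})

test_that("no ms is labeled both whisking and non-whisking on generated data", {
  sk <- default_session()
  for (k in sk$kin[1:15]) {
    ep <- k$epochs
    if (nrow(ep$whisking) && nrow(ep$non_whisking)) {
      ov <- whisktouch:::iv_intersect(ep$whisking, ep$non_whisking)
      expect_equal(nrow(ov), 0L)
    }
  }
})
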