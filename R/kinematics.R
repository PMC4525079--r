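#' Construct a whisker kinematic trace for one trial
#'
#' A trace holds the 1 kHz time series of azimuthal whisker angle
#' \eqn{\theta} (degrees) and whisker curvature \eqn{\kappa} (1/mm, the
#' inverse radius of the osculating circle), together with the behavioral
#' event annotations needed downstream: lick times, the period when the
#' pole is in reach, and touch intervals.  All times are in milliseconds
#' on the 1 ms sampling grid; intervals are half-open \code{[start, end)}.
#'
#' @param trial_id integer trial identifier.
#' @param theta numeric vector, whisker angle in degrees, one sample per ms
#'   starting at t = 0.
#' @param kappa numeric vector, whisker curvature (1/mm), same length as
#'   \code{theta}.
#' @param lick_times numeric vector of lick times (ms), may be empty.
#' @param pole_in_reach length-2 numeric, \code{c(start, end)} ms of the
#'   period when the pole can be touched (the sample epoch).
#' @param touch_intervals two-column matrix of touch \code{[onset, offset)}
#'   intervals in ms; must be non-overlapping and inside the trial.
#' @return An object of class \code{whisker_trace}.
#' @export
whisker_trace <- function(trial_id, theta, kappa = numeric(length(theta)),
                          lick_times = numeric(0),
                          pole_in_reach = c(0, length(theta)),
                          touch_intervals = iv_empty()) {
  n <- length(theta)
  if (n == 0L) stop("empty theta")
  if (length(kappa) != n) stop("theta and kappa lengths differ")
  touch_intervals <- iv(touch_intervals[, 1], touch_intervals[, 2])
  if (nrow(touch_intervals) > 1L) {
    o <- order(touch_intervals[, 1])
    touch_intervals <- touch_intervals[o, , drop = FALSE]
    if (any(touch_intervals[-1, 1] < touch_intervals[-nrow(touch_intervals), 2]))
      stop("overlapping touch intervals")
  }
  if (nrow(touch_intervals) && (min(touch_intervals) < 0 || max(touch_intervals) > n))
    stop("touch intervals outside trial bounds")
  structure(list(trial_id = trial_id, t = seq_len(n) - 1, theta = theta,
                 kappa = kappa, lick_times = sort(lick_times),
                 pole_in_reach = as.numeric(pole_in_reach),
                 touch_intervals = touch_intervals),
            class = "whisker_trace")
}

#' @export
print.whisker_trace <- function(x, ...) {
  cat(sprintf("whisker_trace: trial %s, %d ms, %d touches, %d licks\n",
              x$trial_id, length(x$theta), nrow(x$touch_intervals),
              length(x$lick_times)))
  invisible(x)
}

# Analytic signal via FFT: x + i H[x].  Real input, returns complex vector.
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Decompose a whisker trace into whisking phase and amplitude
#'
#' Bandpasses the whisker angle to the whisking band (6-60 Hz,
#' fourth-order Butterworth, applied forward and backward for zero phase
#' lag) and decomposes the result with the analytic signal.  The
#' instantaneous phase \eqn{\phi \in [-\pi, \pi)} is zero at maximum
#' protraction and \eqn{\pm\pi} at maximum retraction; whisk cycles are
#' delimited at the \eqn{-\pi} crossings so that each cycle spans
#' \eqn{-\pi} to \eqn{\pi}.  Cycles in which the unwrapped phase is not
#' monotonically increasing are flagged.
#'
#' @param trace a [whisker_trace()].
#' @param band length-2 numeric, passband in Hz.
#' @param fs sampling rate in Hz.
#' @return An object of class \code{phase_series} with elements
#'   \code{theta_band}, \code{phi} (radians), \code{amplitude} (degrees,
#'   the analytic-signal envelope) and \code{cycles}, a data frame with
#'   one row per whisk cycle (\code{start}, \code{end} ms, half-open;
#'   \code{p2p} peak-to-peak amplitude of the bandpassed angle within the
#'   cycle; \code{monotonic} flag).
#' @export
decompose_whisking <- function(trace, band = c(6, 60), fs = 1000) {
  theta <- trace$theta
  if (anyNA(theta)) stop("theta contains NA")
  n <- length(theta)
  if (n < 170L) stop("trace too short for bandpass filtering (< 170 ms)")
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  xb <- signal::filtfilt(bf, theta - mean(theta))
  a <- analytic_signal(xb)
  phi <- Arg(a)
  amp <- Mod(a)
  # cycle boundaries: wrap from +pi down to -pi
  wrap <- which(diff(phi) < -pi) + 1L
  cycles <- if (length(wrap) >= 2L) {
    st <- trace$t[wrap[-length(wrap)]]
    en <- trace$t[wrap[-1]]
    p2p <- mono <- numeric(length(st))
    for (k in seq_along(st)) {
      idx <- (wrap[k]):(wrap[k + 1] - 1L)
      p2p[k] <- max(xb[idx]) - min(xb[idx])
      dphi <- diff(phi[idx])
      dphi[dphi < -pi] <- dphi[dphi < -pi] + 2 * pi
      mono[k] <- all(dphi > -1e-9)
    }
    data.frame(start = st, end = en, p2p = p2p, monotonic = as.logical(mono))
  } else {
    data.frame(start = numeric(0), end = numeric(0), p2p = numeric(0),
               monotonic = logical(0))
  }
  structure(list(trial_id = trace$trial_id, t = trace$t, theta_band = xb,
                 phi = phi, amplitude = amp, cycles = cycles, fs = fs),
            class = "phase_series")
}

#' Segment a trial into whisking, non-whisking and exploration epochs
#'
#' Whisking epochs are whisk cycles whose peak-to-peak bandpassed
#' amplitude exceeds \code{whisk_p2p_min} (2.5 degrees).  Cycles during
#' licking or beginning less than \code{touch_exclusion} ms after a touch
#' are retained as whisking time but flagged unusable for phase analyses
#' (\code{phase_ok}), as are cycles with non-monotonic phase or cycles
#' overlapping a touch.  Non-whisking epochs are contiguous stretches of
#' at least \code{quiet_min} ms with envelope amplitude below
#' \code{quiet_amp_max} (1.25 degrees) and no touch or lick.  Exploration
#' epochs are the union of whisking and touch epochs (touches longer than
#' \code{prolonged_touch} ms removed), restricted to the period when the
#' pole is in reach.
#'
#' @param trace a [whisker_trace()].
#' @param phase the [decompose_whisking()] output for the same trace.
#' @param whisk_p2p_min,quiet_amp_max degrees; see Description.
#' @param quiet_min,touch_exclusion,prolonged_touch ms; see Description.
#' @return An object of class \code{epoch_set}: interval matrices
#'   \code{whisking}, \code{non_whisking}, \code{touch},
#'   \code{exploration}, and the cycle table \code{cycles} with added
#'   columns \code{whisking} and \code{phase_ok}.
#' @export
segment_epochs <- function(trace, phase, whisk_p2p_min = 2.5,
                           quiet_amp_max = 1.25, quiet_min = 100,
                           touch_exclusion = 70, prolonged_touch = 100) {
  cyc <- phase$cycles
  touches <- trace$touch_intervals
  cyc$whisking <- cyc$p2p > whisk_p2p_min

  overlaps_any <- function(st, en, ivx) {
    if (nrow(ivx) == 0L) return(rep(FALSE, length(st)))
    vapply(seq_along(st), function(k)
      any(ivx[, 1] < en[k] & ivx[, 2] > st[k]), logical(1))
  }
  # touch shadow: the touch itself plus touch_exclusion ms after it
  shadow <- if (nrow(touches)) iv(touches[, 1], touches[, 2] + touch_exclusion)
            else iv_empty()
  lick_hit <- if (length(trace$lick_times)) vapply(seq_len(nrow(cyc)), function(k)
    any(trace$lick_times >= cyc$start[k] & trace$lick_times < cyc$end[k]),
    logical(1)) else rep(FALSE, nrow(cyc))
  cyc$phase_ok <- cyc$whisking & cyc$monotonic & !lick_hit &
    !overlaps_any(cyc$start, cyc$end, shadow)

  # Whisking time = qualifying cycles, trimmed to samples where the
  # envelope is at least the quiet threshold.  The trim drops the tail of
  # boundary "cycles" that extend into quiet periods (where the phase of
  # near-zero noise wraps slowly), and makes whisking and non-whisking
  # disjoint by construction.
  whisking <- if (any(cyc$whisking)) {
    env_ok <- phase$amplitude >= quiet_amp_max
    r0 <- rle(env_ok)
    e0 <- cumsum(r0$lengths)
    s0 <- e0 - r0$lengths + 1L
    env_iv <- if (any(r0$values))
      iv(trace$t[s0[r0$values]], trace$t[e0[r0$values]] + 1) else iv_empty()
    iv_intersect(iv_union(iv(cyc$start[cyc$whisking], cyc$end[cyc$whisking])),
                 env_iv)
  } else iv_empty()

  # non-whisking: quiet envelope, no touch or lick, >= quiet_min ms
  ok <- phase$amplitude < quiet_amp_max
  if (nrow(touches)) ok[in_iv(trace$t, touches)] <- FALSE
  for (lt in trace$lick_times) {
    i <- floor(lt) + 1L
    if (i >= 1L && i <= length(ok)) ok[i] <- FALSE
  }
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= quiet_min
  non_whisking <- if (any(keep))
    iv(trace$t[starts[keep]], trace$t[ends[keep]] + 1) else iv_empty()

  short_touch <- if (nrow(touches))
    touches[(touches[, 2] - touches[, 1]) <= prolonged_touch, , drop = FALSE]
  else iv_empty()
  exploration <- iv_intersect(iv_union(rbind(whisking, short_touch)),
                              iv(trace$pole_in_reach[1], trace$pole_in_reach[2]))

  structure(list(whisking = whisking, non_whisking = non_whisking,
                 touch = touches, exploration = exploration, cycles = cyc),
            class = "epoch_set")
}

#' Per-touch stimulus features
#'
#' For every touch interval of a trace, computes the touch order within
#' the trial, the inter-contact interval (time since the previous touch
#' offset; \code{Inf} for the first touch), the pretouch whisker velocity
#' (least-squares slope of \eqn{\theta} over the 5 ms ending at onset, in
#' degrees/ms), and the maximum absolute curvature change
#' \code{max_dkappa} within \code{[onset, onset + 20)} ms relative to the
#' pre-touch baseline (median \eqn{\kappa} over the 10 ms before onset).
#'
#' @param trace a [whisker_trace()].
#' @param vel_window,dkappa_window,baseline_window window lengths in ms.
#' @return data frame with one row per touch: \code{trial_id},
#'   \code{onset}, \code{offset}, \code{order}, \code{ici},
#'   \code{pretouch_velocity} (NA if the touch starts too early to
#'   estimate), \code{max_dkappa}, \code{is_first}.
#' @export
extract_touch_features <- function(trace, vel_window = 5, dkappa_window = 20,
                                   baseline_window = 10) {
  tv <- trace$touch_intervals
  n_t <- nrow(tv)
  if (n_t == 0L)
    return(data.frame(trial_id = integer(0), onset = numeric(0),
                      offset = numeric(0), order = integer(0), ici = numeric(0),
                      pretouch_velocity = numeric(0), max_dkappa = numeric(0),
                      is_first = logical(0)))
  n <- length(trace$theta)
  vel <- dk <- numeric(n_t)
  for (i in seq_len(n_t)) {
    on <- tv[i, 1]
    idx <- which(trace$t >= on - vel_window & trace$t < on)
    vel[i] <- if (length(idx) >= 2L) {
      tt <- trace$t[idx]
      stats::cov(tt, trace$theta[idx]) / stats::var(tt)
    } else NA_real_
    bidx <- which(trace$t >= on - baseline_window & trace$t < on)
    kb <- if (length(bidx)) stats::median(trace$kappa[bidx]) else trace$kappa[on + 1]
    widx <- which(trace$t >= on & trace$t < min(on + dkappa_window, n))
    dk[i] <- max(abs(trace$kappa[widx] - kb))
  }
  data.frame(trial_id = trace$trial_id, onset = tv[, 1], offset = tv[, 2],
             order = seq_len(n_t),
             ici = c(Inf, tv[-1, 1] - tv[-n_t, 2]),
             pretouch_velocity = vel, max_dkappa = dk,
             is_first = seq_len(n_t) == 1L)
}

#' Reaction time of a trial
#'
#' Time from the first touch onset to the first lick.  Undefined
#' (\code{NA}) when the trial has no touch or no lick.  A lick preceding
#' the first touch yields a negative value, flagged with the attribute
#' \code{premature}.
#'
#' @param trace a [whisker_trace()].
#' @return reaction time in ms, or \code{NA_real_}.
#' @export
reaction_time <- function(trace) {
  if (nrow(trace$touch_intervals) == 0L || length(trace$lick_times) == 0L)
    return(NA_real_)
  rt <- unname(min(trace$lick_times) - trace$touch_intervals[1, 1])
  if (rt < 0) attr(rt, "premature") <- TRUE
  rt
}
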