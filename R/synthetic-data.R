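#' Configuration of the synthetic session generator
#'
#' Defines the generative model used to emulate single-whisker object
#' localization sessions: whisking bouts with rhythmic oscillation,
#' touches placed at protraction peaks while the pole is in reach,
#' touch-triggered curvature transients, licking after the first touch,
#' and a three-component spike process (touch-evoked, phase-coupled and
#' baseline spikes) with an absolute refractory period.  Defaults are
#' calibrated to the behavioral statistics of head-fixed mice localizing
#' a pole with a single whisker: 261 ms mean bout duration, 15.7 degree
#' peak-to-peak whisking amplitude, 15.4 Hz whisking frequency, 2.33
#' touches per trial, sub-second reaction times, and a low-rate L4-like
#' neuron firing roughly one spike per touch at 8 ms latency with
#' cosine phase tuning of depth 0.5.
#'
#' @param n_trials number of trials.
#' @param trial_duration trial length in ms (1 kHz sampling grid).
#' @param sample_epoch length-2 ms interval when the pole is in reach.
#' @param whisk_freq,whisk_freq_sd mean and per-cycle s.d. of the
#'   whisking frequency (Hz).
#' @param whisk_p2p_amp,whisk_amp_sd mean and per-bout s.d. of the
#'   peak-to-peak whisking amplitude (degrees); 0 disables whisking.
#' @param bout_duration_mean,bout_duration_shape gamma mean (ms) and
#'   shape of whisking-bout durations.
#' @param bout_gap_mean mean (ms) of exponential inter-bout pauses.
#' @param whisk_ramp length (ms) of the raised-cosine amplitude ramp at
#'   each end of a bout.  The drawn bout duration is interpreted as the
#'   time the envelope exceeds the 1.25 degree quiet threshold, so the
#'   generated oscillation is extended by the analytic sub-threshold
#'   ramp time at each end.
#' @param setpoint_amp,setpoint_freq slow setpoint oscillation of the
#'   whisker angle (degrees, Hz).
#' @param theta_noise_sd measurement noise on theta (degrees).
#' @param touches_per_trial_mean expected touches per trial; 0 disables
#'   touches.
#' @param touch_dispersion gamma shape of the per-trial touch-propensity
#'   multiplier; smaller values give more across-trial variability in
#'   touch counts (1.5 approximates the broad empirical distribution).
#' @param touch_duration_mean,touch_duration_shape gamma mean (ms) and
#'   shape of touch durations (occasional touches exceed 100 ms,
#'   exercising the prolonged-touch exclusion).
#' @param touch_phase_lead_max touches start up to this many ms before
#'   the protraction peak (uniform), giving positive pretouch velocities.
#' @param dkappa_meanlog,dkappa_sdlog log-normal parameters of the peak
#'   touch-induced curvature change (1/mm).
#' @param lick_prob probability that a trial with touches has licks.
#' @param lick_rate lick rate (Hz) once licking starts.
#' @param lick_train_duration duration (ms) of the lick train.
#' @param reaction_mean,reaction_sd gamma mean and s.d. (ms) of the
#'   reaction time (first touch to first lick).
#' @param baseline_rate homogeneous baseline spike rate (spikes/s).
#' @param touch_spike_prob,touch_spike_prob_later per-touch spike
#'   probability (binomial model) or mean count (poisson model) for
#'   first and later touches.
#' @param touch_latency latency (ms) from touch onset to the evoked
#'   spike.
#' @param touch_jitter s.d. (ms) of the spike-latency jitter.  Jitter is
#'   gamma-distributed (shape 2) so latencies are right-skewed with a
#'   hard floor at \code{touch_latency}, as in sensory conduction delays.
#' @param phase_A,phase_B cosine tuning parameters (spikes/s): during
#'   whisking the phase-coupled rate is
#'   \eqn{A[1 + \cos(\phi - \phi_{pref})] + B}; the modulation depth is
#'   A/(A+B).
#' @param phase_pref preferred phase (radians; 0 = maximum protraction).
#' @param refractory absolute refractory period (ms); spikes closer than
#'   this to the preceding spike are deleted (earlier spike kept).
#' @param count_model \code{"binomial"} (0/1 spikes per touch) or
#'   \code{"poisson"} (unbounded counts).
#' @param feature_effects named numeric gains \code{c(order=, velocity=,
#'   max_dkappa=)} of a log-linear link from standardized touch features
#'   to the per-touch spike probability (clipped to \[0, 1\] under the
#'   binomial model).  All zero by default: responses are then
#'   feature-independent and the mean spikes/touch equals the base
#'   probability.
#' @param seed integer; fully determines the generated session.
#' @return object of class \code{generator_config}.
#' @export
generator_config <- function(n_trials = 50,
                             trial_duration = 4000,
                             sample_epoch = c(1000, 3400),
                             whisk_freq = 15.4, whisk_freq_sd = 2,
                             whisk_p2p_amp = 15.7, whisk_amp_sd = 2,
                             bout_duration_mean = 261, bout_duration_shape = 4,
                             bout_gap_mean = 220, whisk_ramp = 20,
                             setpoint_amp = 2, setpoint_freq = 0.3,
                             theta_noise_sd = 0.2,
                             touches_per_trial_mean = 2.33,
                             touch_dispersion = 1.5,
                             touch_duration_mean = 45, touch_duration_shape = 2,
                             touch_phase_lead_max = 15,
                             dkappa_meanlog = log(0.003), dkappa_sdlog = 0.4,
                             lick_prob = 0.7, lick_rate = 7,
                             lick_train_duration = 1000,
                             reaction_mean = 367, reaction_sd = 234,
                             baseline_rate = 0.02,
                             touch_spike_prob = 0.7,
                             touch_spike_prob_later = 0.7,
                             touch_latency = 8, touch_jitter = 1,
                             phase_A = 0.26, phase_B = 0.26, phase_pref = 0,
                             refractory = 2.3,
                             count_model = c("binomial", "poisson"),
                             feature_effects = c(order = 0, velocity = 0,
                                                 max_dkappa = 0),
                             seed = 1L) {
  count_model <- match.arg(count_model)
  cfg <- as.list(environment())
  if (trial_duration <= 0) stop("invalid config: non-positive trial_duration")
  if (diff(sample_epoch) <= 0 || sample_epoch[1] < 0 ||
      sample_epoch[2] > trial_duration)
    stop("invalid config: sample_epoch must be a positive interval inside the trial")
  nonneg <- c("whisk_freq", "whisk_p2p_amp", "bout_duration_mean",
              "bout_gap_mean", "touches_per_trial_mean", "baseline_rate",
              "touch_spike_prob", "touch_spike_prob_later", "touch_latency",
              "touch_jitter", "phase_A", "phase_B", "refractory")
  for (f in nonneg)
    if (cfg[[f]] < 0) stop("invalid config: ", f, " must be non-negative")
  if (count_model == "binomial" &&
      (touch_spike_prob > 1 || touch_spike_prob_later > 1))
    stop("invalid config: touch_spike_prob must be <= 1 under the binomial model")
  fe <- c(order = 0, velocity = 0, max_dkappa = 0)
  fe[names(feature_effects)] <- feature_effects
  cfg$feature_effects <- fe
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf(paste0("generator_config: %d trials x %d ms, %.2f touches/trial,",
                     " p(spike|touch) = %.2f (%s), depth = %.2f, seed = %d\n"),
              x$n_trials, x$trial_duration, x$touches_per_trial_mean,
              x$touch_spike_prob, x$count_model,
              if (x$phase_A + x$phase_B > 0) x$phase_A / (x$phase_A + x$phase_B)
              else NA, x$seed))
  invisible(x)
}

#' Generate the whisker trace of one trial
#'
#' Builds theta as a slow setpoint plus bout-gated rhythmic oscillation
#' (raised-cosine amplitude ramps, per-cycle frequency jitter), places
#' touches near protraction peaks while the pole is in reach (thinned to
#' the configured mean touch count, with a gamma-distributed per-trial
#' propensity giving overdispersed touch counts), and adds a
#' ramp-hold-release curvature transient to kappa for every touch
#' (10 ms linear rise, plateau to touch offset, exponential release).
#' Licks start one reaction time after the first touch on a fraction of
#' trials.  Fully determined by \code{config$seed} and
#' \code{trial_index}.
#'
#' @param config a [generator_config()].
#' @param trial_index 1-based trial number.
#' @return a [whisker_trace()].
#' @export
generate_whisker_trace <- function(config, trial_index) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(derive_seed(config$seed, 1000000 + trial_index), {
    n <- as.integer(config$trial_duration)
    t <- seq_len(n) - 1
    setpt <- config$setpoint_amp *
      sin(2 * pi * config$setpoint_freq * t / 1000 + runif(1, 0, 2 * pi))
    theta <- setpt + rnorm(n, 0, config$theta_noise_sd)
    peaks <- numeric(0)

    if (config$whisk_p2p_amp > 0) {
      pos <- -runif(1, 0, config$bout_gap_mean)  # random phase of bout process
      while (pos < n) {
        gap <- rexp(1, 1 / config$bout_gap_mean)
        dur <- rgamma(1, shape = config$bout_duration_shape,
                      scale = config$bout_duration_mean / config$bout_duration_shape)
        # 0.98: calibration for bandpass-edge overshoot, which inflates the
        # measured maximum cycle peak-to-peak amplitude by ~2% of the bout
        # amplitude; with the correction the emitted per-bout maximum
        # amplitude averages the configured value.
        amp_pre <- 0.98 * max(3, rnorm(1, config$whisk_p2p_amp, config$whisk_amp_sd))
        # sub-threshold portion of the raised-cosine ramp (envelope < 1.25 deg)
        u_star <- (config$whisk_ramp / pi) *
          acos(max(-1, min(1, 1 - 2 * (2.5 / amp_pre))))
        dur <- dur + 2 * u_star
        b0 <- pos + gap
        b1 <- min(b0 + dur, n)
        pos <- b0 + dur
        if (b1 - b0 < 40 || b0 >= n - 1) next
        amp2 <- amp_pre
        i0 <- max(1L, floor(b0) + 1L)
        i1 <- min(n, ceiling(b1))
        len <- i1 - i0 + 1L
        if (len < 40L) next
        # per-cycle frequency jitter: piecewise-constant instantaneous freq
        freqs <- numeric(0)
        tot <- 0
        while (tot < len) {
          f <- max(6, min(30, rnorm(1, config$whisk_freq, config$whisk_freq_sd)))
          L <- max(2L, round(1000 / f))
          freqs <- c(freqs, rep(f, L))
          tot <- tot + L
        }
        freqs <- freqs[seq_len(len)]
        ph <- -pi + cumsum(2 * pi * freqs / 1000)
        ramp <- config$whisk_ramp
        u <- seq_len(len) - 1
        env <- pmin(1, pmin(u, rev(u)) / ramp)
        env <- (1 - cos(pi * pmin(1, env))) / 2
        osc <- (amp2 / 2) * env * cos(ph)
        theta[i0:i1] <- theta[i0:i1] + osc
        # protraction peaks: phase crossings of 0 (mod 2pi) with usable envelope
        k <- which(diff(ph %% (2 * pi)) < -pi)
        if (length(k)) {
          pk <- t[i0 + k - 1L]
          peaks <- c(peaks, pk[env[k] > 0.5])
        }
      }
    }

    kappa <- numeric(n)
    touch_iv <- iv_empty()
    if (config$touches_per_trial_mean > 0 && length(peaks)) {
      reach <- config$sample_epoch
      cand <- peaks[peaks >= reach[1] + config$touch_phase_lead_max &
                    peaks < reach[2]]
      if (length(cand)) {
        u <- rgamma(1, shape = config$touch_dispersion,
                    rate = config$touch_dispersion)
        q <- min(1, u * config$touches_per_trial_mean / length(cand))
        keep <- cand[runif(length(cand)) < q]
        if (length(keep)) {
          onset <- sort(round(keep - runif(length(keep), 0,
                                           config$touch_phase_lead_max)))
          dur <- rgamma(length(onset), shape = config$touch_duration_shape,
                        scale = config$touch_duration_mean /
                          config$touch_duration_shape)
          offset <- onset + pmax(3, round(dur))
          if (length(onset) > 1L)  # truncate to keep touches disjoint
            offset[-length(offset)] <- pmin(offset[-length(offset)],
                                            onset[-1] - 2)
          offset <- pmin(offset, n - 1)
          ok <- offset > onset
          onset <- onset[ok]; offset <- offset[ok]
          if (length(onset)) {
            touch_iv <- iv(onset, offset)
            peak_dk <- rlnorm(length(onset), config$dkappa_meanlog,
                              config$dkappa_sdlog)
            for (j in seq_along(onset)) {
              on <- onset[j]; off <- offset[j]
              rise_end <- min(on + 10, off)
              idx <- which(t >= on & t < off)
              prof <- pmin(1, (t[idx] - on) / max(1, rise_end - on))
              kappa[idx] <- kappa[idx] + peak_dk[j] * prof
              ridx <- which(t >= off & t < min(off + 30, n,
                            if (j < length(onset)) onset[j + 1] else n))
              if (length(ridx))
                kappa[ridx] <- kappa[ridx] +
                  peak_dk[j] * exp(-(t[ridx] - off) / 10)
            }
          }
        }
      }
    }

    licks <- numeric(0)
    if (nrow(touch_iv) && runif(1) < config$lick_prob) {
      sh <- (config$reaction_mean / config$reaction_sd)^2
      rt <- rgamma(1, shape = sh, scale = config$reaction_mean / sh)
      first <- touch_iv[1, 1] + rt
      if (first < n - 1) {
        gaps <- rexp(50, config$lick_rate / 1000)
        licks <- first + c(0, cumsum(gaps))
        licks <- round(licks[licks < min(n - 1, first + config$lick_train_duration)])
      }
    }

    whisker_trace(trial_id = trial_index, theta = theta, kappa = kappa,
                  lick_times = licks,
                  pole_in_reach = config$sample_epoch,
                  touch_intervals = touch_iv)
  })
}

# Per-touch spike probabilities with the log-linear feature link.
# Features are standardized against fixed reference scales (velocity:
# 0.45 +/- 0.25 deg/ms, typical of protraction-onset touches at the
# default amplitude and frequency; curvature: the configured log-normal;
# order: 2 +/- 1.5).  With nonzero gains the realized mean spikes/touch
# deviates from the base probability; gains are zero by default.
touch_spike_probs <- function(touches, config) {
  p <- ifelse(touches$is_first, config$touch_spike_prob,
              config$touch_spike_prob_later)
  fe <- config$feature_effects
  if (any(fe != 0) && nrow(touches) > 0) {
    z_ord <- (touches$order - 2) / 1.5
    z_vel <- (touches$pretouch_velocity - 0.45) / 0.25
    z_vel[is.na(z_vel)] <- 0
    z_dk <- (log(pmax(touches$max_dkappa, 1e-8)) - config$dkappa_meanlog) /
      config$dkappa_sdlog
    lin <- fe["order"] * z_ord + fe["velocity"] * z_vel + fe["max_dkappa"] * z_dk
    p <- p * exp(lin)
  }
  if (config$count_model == "binomial") p <- pmin(1, pmax(0, p))
  unname(p)
}

#' Generate spikes for one trial
#'
#' Spikes are the union of three labelled processes: (i) touch-evoked
#' spikes, drawn per touch under the configured count model with latency
#' \code{touch_latency} plus gamma jitter and probability optionally
#' modulated by touch features; (ii) phase-coupled spikes from an
#' inhomogeneous Poisson process with rate
#' \eqn{A[1+\cos(\phi-\phi_{pref})]+B} during whisking cycles; (iii) a
#' homogeneous baseline Poisson process.  Spikes closer than the
#' refractory period to the preceding spike are deleted (forward
#' deletion, earlier spike kept) and logged.
#'
#' @param trace the trial's [whisker_trace()].
#' @param touches the touch table from [extract_touch_features()] (the
#'   generator augments it internally with its latent features).
#' @param phase the [decompose_whisking()] output for the trace.
#' @param config a [generator_config()].
#' @return list with \code{spikes} (sorted times, ms),
#'   \code{ground_truth} (data frame \code{time}, \code{label} in
#'   \{touch, phase, baseline\}, for spikes surviving the refractory
#'   deletion) and \code{deleted} (count of refractory deletions).
#' @export
generate_spikes <- function(trace, touches, phase, config) {
  stopifnot(inherits(config, "generator_config"))
  if (config$touch_latency < 0) stop("invalid config: negative latency")
  with_seed(derive_seed(config$seed, 2000000 + trace$trial_id), {
    n <- length(trace$theta)
    times <- numeric(0); labels <- character(0)

    if (nrow(touches)) {
      p <- touch_spike_probs(touches, config)
      counts <- if (config$count_model == "binomial")
        stats::rbinom(nrow(touches), 1L, p) else stats::rpois(nrow(touches), p)
      for (j in which(counts > 0)) {
        jit <- if (config$touch_jitter > 0)
          stats::rgamma(counts[j], shape = 2,
                        scale = config$touch_jitter / sqrt(2)) else
          rep(0, counts[j])
        ts <- touches$onset[j] + config$touch_latency + jit
        times <- c(times, ts)
        labels <- c(labels, rep("touch", counts[j]))
      }
    }

    wcyc <- phase$cycles[phase$cycles$p2p > 2.5, , drop = FALSE]
    lam_max <- 2 * config$phase_A + config$phase_B
    if (nrow(wcyc) && lam_max > 0) {
      wiv <- iv_union(iv(wcyc$start, wcyc$end))
      dur_s <- iv_duration(wiv) / 1000
      m <- stats::rpois(1, lam_max * dur_s)
      if (m > 0) {
        cand <- runif_iv(m, wiv)
        ph <- phase$phi[pmin(length(phase$phi), floor(cand) + 1L)]
        lam <- config$phase_A * (1 + cos(ph - config$phase_pref)) + config$phase_B
        acc <- cand[runif(m) < lam / lam_max]
        times <- c(times, acc)
        labels <- c(labels, rep("phase", length(acc)))
      }
    }

    if (config$baseline_rate > 0) {
      m <- stats::rpois(1, config$baseline_rate * n / 1000)
      if (m > 0) {
        ts <- runif(m, 0, n)
        times <- c(times, ts)
        labels <- c(labels, rep("baseline", m))
      }
    }

    o <- order(times)
    times <- round(times[o], 3); labels <- labels[o]
    keep <- rep(TRUE, length(times))
    if (length(times) > 1L && config$refractory > 0) {
      last <- times[1]
      for (i in 2:length(times)) {
        if (times[i] - last < config$refractory) keep[i] <- FALSE
        else last <- times[i]
      }
    }
    list(spikes = times[keep],
         ground_truth = data.frame(time = times[keep], label = labels[keep],
                                   stringsAsFactors = FALSE),
         deleted = sum(!keep))
  })
}

#' Generate a full synthetic session
#'
#' Runs the per-trial generators for all trials and assembles a session
#' object: whisker traces, touch tables (with kinematic features from
#' [extract_touch_features()]), spike times and per-spike ground-truth
#' labels.  Identical configurations (including the seed) give identical
#' sessions.
#'
#' @param config a [generator_config()].
#' @return object of class \code{wt_session}: list with \code{manifest},
#'   \code{config}, \code{traces} (list of [whisker_trace()]),
#'   \code{touches} (data frame over all trials), \code{spikes}
#'   (data frame \code{trial_id}, \code{time}), \code{ground_truth},
#'   and \code{truth} (the generative parameter values: per-touch spike
#'   probabilities, modulation depth A/(A+B), preferred phase, latency).
#' @export
generate_session <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  traces <- vector("list", config$n_trials)
  touch_list <- spike_list <- gt_list <- vector("list", config$n_trials)
  deleted <- 0L
  for (i in seq_len(config$n_trials)) {
    tr <- generate_whisker_trace(config, i)
    ph <- decompose_whisking(tr)
    tf <- extract_touch_features(tr)
    sp <- generate_spikes(tr, tf, ph, config)
    traces[[i]] <- tr
    touch_list[[i]] <- tf
    spike_list[[i]] <- if (length(sp$spikes))
      data.frame(trial_id = i, time = sp$spikes) else NULL
    gt_list[[i]] <- if (nrow(sp$ground_truth))
      cbind(trial_id = i, sp$ground_truth) else NULL
    deleted <- deleted + sp$deleted
  }
  denom <- config$phase_A + config$phase_B
  structure(list(
    manifest = list(session_id = sprintf("synthetic-%d", config$seed),
                    schema_version = 1L,
                    n_trials = config$n_trials,
                    trial_duration = config$trial_duration,
                    cell = list(layer = "L4", in_column = TRUE,
                                depth_um = 450)),
    config = config,
    traces = traces,
    touches = do.call(rbind, touch_list),
    spikes = do.call(rbind, spike_list) %||%
      data.frame(trial_id = integer(0), time = numeric(0)),
    ground_truth = do.call(rbind, gt_list) %||%
      data.frame(trial_id = integer(0), time = numeric(0),
                 label = character(0)),
    deleted = deleted,
    truth = list(p_first = config$touch_spike_prob,
                 p_later = config$touch_spike_prob_later,
                 depth = if (denom > 0) config$phase_A / denom else NA_real_,
                 phase_pref = config$phase_pref,
                 latency = config$touch_latency)),
    class = "wt_session")
}

#' @export
print.wt_session <- function(x, ...) {
  cat(sprintf("wt_session %s: %d trials, %d touches, %d spikes\n",
              x$manifest$session_id, x$manifest$n_trials,
              if (is.null(x$touches)) 0L else nrow(x$touches),
              nrow(x$spikes)))
  invisible(x)
}
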