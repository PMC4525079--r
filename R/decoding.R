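# Resampling-based population decoding of touch presence, time since
# touch, and whisking phase.  Populations are assembled by sampling
# neurons with replacement and pooling their integrated spike counts;
# responses are assumed independent across neurons.

#' Touch-aligned response segments of one neuron
#'
#' Extracts spike times relative to each touch onset in a window from
#' \code{pre} ms before to \code{post} ms after touch, excluding touches
#' followed by a second touch within the post window (their responses
#' would be contaminated by the next contact).
#'
#' @param spikes data frame \code{trial_id}, \code{time}.
#' @param touches touch table.
#' @param pre,post window bounds in ms.
#' @return list of numeric vectors, one per retained touch.
#' @export
touch_segments <- function(spikes, touches, pre = 30, post = 50) {
  keep <- rep(TRUE, nrow(touches))
  for (i in seq_len(nrow(touches))) {
    nxt <- touches$onset[touches$trial_id == touches$trial_id[i] &
                           touches$onset > touches$onset[i]]
    if (length(nxt) && min(nxt) - touches$onset[i] <= post) keep[i] <- FALSE
  }
  tt <- touches[keep, , drop = FALSE]
  lapply(seq_len(nrow(tt)), function(i) {
    st <- spikes$time[spikes$trial_id == tt$trial_id[i]] - tt$onset[i]
    st[st >= -pre & st <= post]
  })
}

# Causally integrated counts: matrix (n_segments x n_timepoints); entry
# [j, k] counts spikes in (t_k - w, t_k].
integrate_segments <- function(segments, w = 10, t_grid = seq(-30, 50)) {
  m <- matrix(0L, nrow = length(segments), ncol = length(t_grid))
  for (j in seq_along(segments)) {
    s <- segments[[j]]
    if (length(s))
      m[j, ] <- vapply(t_grid, function(tk)
        sum(s > tk - w & s <= tk), integer(1))
  }
  m
}

#' Build a decoder neuron from touch responses and non-touch counts
#'
#' A decoder neuron holds resampled integrated responses: a matrix of
#' touch-aligned counts (draws x time points) and a vector of counts in
#' windows without touch.  [decoder_neuron_from_session()] builds one
#' from a session; this constructor accepts precomputed matrices (used
#' for parametric populations in simulations).
#'
#' @param touch_counts integer matrix, draws x time points.
#' @param nontouch_counts integer vector of draws.
#' @param t_grid time points (ms relative to touch onset).
#' @return object of class \code{decoder_neuron}.
#' @export
decoder_neuron <- function(touch_counts, nontouch_counts,
                           t_grid = seq(-30, 50)) {
  stopifnot(ncol(touch_counts) == length(t_grid))
  structure(list(touch_counts = touch_counts,
                 nontouch_counts = nontouch_counts, t_grid = t_grid),
            class = "decoder_neuron")
}

#' @rdname decoder_neuron
#' @param session,kin session and kinematics; see [session_kinematics()].
#' @param w causal integration window (ms).
#' @param n_draw resampled responses per neuron.
#' @param buffer minimum distance (ms) of non-touch windows from any
#'   touch.
#' @param seed RNG seed.
#' @export
decoder_neuron_from_session <- function(session, kin, w = 10, n_draw = 1000,
                                        buffer = 100, seed = NULL,
                                        t_grid = seq(-30, 50)) {
  with_seed(seed, {
    segs <- touch_segments(session$spikes, session$touches)
    if (length(segs) == 0L) stop("no usable touches")
    m <- integrate_segments(segs, w, t_grid)
    draws <- m[sample.int(nrow(m), n_draw, replace = TRUE), , drop = FALSE]
    # non-touch windows: exploration time >= buffer away from touches
    nt <- numeric(0)
    for (tid in names(kin)) {
      expl <- kin[[tid]]$epochs$exploration
      tch <- kin[[tid]]$epochs$touch
      if (nrow(tch))
        expl <- iv_setdiff(expl, iv(tch[, 1] - buffer, tch[, 2] + buffer))
      if (nrow(expl) == 0L) next
      st <- session$spikes$time[session$spikes$trial_id == as.integer(tid)]
      k <- ceiling(n_draw / length(kin))
      t0 <- runif_iv(k, expl)
      nt <- c(nt, vapply(t0, function(tk) sum(st > tk - w & st <= tk),
                         numeric(1)))
    }
    if (length(nt) == 0L) nt <- 0
    nontouch <- nt[sample.int(length(nt), n_draw, replace = TRUE)]
    decoder_neuron(draws, nontouch, t_grid)
  })
}

#' Touch detection by a one-dimensional linear decoder
#'
#' At each time point around touch, pools the integrated counts of
#' \code{n} neurons (sampled with replacement, so populations larger
#' than the available set are allowed) and discriminates touch from
#' non-touch epochs with a threshold on the pooled count.  The
#' threshold is optimized on a training half (maximizing balanced
#' accuracy) and performance is evaluated on the held-out half;
#' repetitions over random neuron/response draws give the bounds.
#'
#' @param neurons list of [decoder_neuron()] objects.
#' @param n_grid population sizes to evaluate.
#' @param n_rep repetitions per population size.
#' @param n_eval pooled samples per class per repetition (half train,
#'   half test).
#' @param seed RNG seed.
#' @return object of class \code{decoder_result} (task "presence"):
#'   \code{by_time} (data frame \code{n}, \code{t}, \code{accuracy},
#'   \code{hit_rate} averaged over repetitions), \code{performance}
#'   (data frame \code{n}, \code{accuracy}, \code{hit_rate}, \code{lo},
#'   \code{hi} at the best time point).
#' @export
decode_touch_presence <- function(neurons, n_grid = c(1, 2, 5, 10, 15, 20),
                                  n_rep = 20, n_eval = 400, seed = NULL) {
  t_grid <- neurons[[1]]$t_grid
  with_seed(seed, {
    by_time <- list()
    perf <- list()
    for (n in n_grid) {
      acc_rep <- matrix(NA_real_, n_rep, length(t_grid))
      hit_rep <- matrix(NA_real_, n_rep, length(t_grid))
      for (r in seq_len(n_rep)) {
        ids <- sample.int(length(neurons), n, replace = TRUE)
        pooled_t <- matrix(0L, n_eval, length(t_grid))
        pooled_n <- numeric(n_eval)
        for (i in ids) {
          nn <- neurons[[i]]
          rows <- sample.int(nrow(nn$touch_counts), n_eval, replace = TRUE)
          pooled_t <- pooled_t + nn$touch_counts[rows, , drop = FALSE]
          pooled_n <- pooled_n +
            nn$nontouch_counts[sample.int(length(nn$nontouch_counts), n_eval,
                                          replace = TRUE)]
        }
        half <- n_eval %/% 2
        tr_idx <- seq_len(half)
        te_idx <- (half + 1):n_eval
        for (k in seq_along(t_grid)) {
          xt <- pooled_t[, k]
          thr_cand <- 0:max(xt[tr_idx], pooled_n[tr_idx])
          bal <- vapply(thr_cand, function(th)
            (mean(xt[tr_idx] > th) + mean(pooled_n[tr_idx] <= th)) / 2,
            numeric(1))
          th <- thr_cand[which.max(bal)]
          hit <- mean(xt[te_idx] > th)
          cr <- mean(pooled_n[te_idx] <= th)
          acc_rep[r, k] <- (hit + cr) / 2
          hit_rep[r, k] <- hit
        }
      }
      acc <- colMeans(acc_rep)
      best_k <- which.max(acc)
      by_time[[length(by_time) + 1L]] <-
        data.frame(n = n, t = t_grid, accuracy = acc, hit_rate = colMeans(hit_rep))
      perf[[length(perf) + 1L]] <-
        data.frame(n = n, accuracy = acc[best_k],
                   hit_rate = mean(hit_rep[, best_k]),
                   lo = stats::quantile(acc_rep[, best_k], 0.025, names = FALSE),
                   hi = stats::quantile(acc_rep[, best_k], 0.975, names = FALSE))
    }
    structure(list(task = "presence", by_time = do.call(rbind, by_time),
                   performance = do.call(rbind, perf)),
              class = "decoder_result")
  })
}

#' Decoding time since touch with a multinomial naive Bayes classifier
#'
#' Treats each time point in the touch-aligned window as a class; the
#' observation is the pooled causally-integrated count of \code{n}
#' neurons.  Count likelihoods per class are estimated from a training
#' set of pooled draws (histogram with add-one smoothing); predictions
#' are maximum a posteriori under a uniform prior.  The root mean
#' square error between decoded and true elapsed time is reported per
#' class and overall, with bootstrap bounds.
#'
#' @param neurons list of [decoder_neuron()] objects.
#' @param n_grid population sizes.
#' @param n_boot bootstrap runs.
#' @param m_train,m_test pooled draws per class for training/testing.
#' @param seed RNG seed.
#' @return \code{decoder_result} (task "time"): \code{performance}
#'   (data frame \code{n}, \code{rms_ms}, \code{lo}, \code{hi}),
#'   \code{by_time} (RMS error per true time, largest n).
#' @export
decode_touch_time <- function(neurons, n_grid = c(10, 50, 200), n_boot = 100,
                              m_train = 100, m_test = 100, seed = NULL) {
  t_grid <- neurons[[1]]$t_grid
  nt <- length(t_grid)
  pool_draws <- function(n, m) {
    ids <- sample.int(length(neurons), n, replace = TRUE)
    P <- matrix(0L, m, nt)
    for (i in ids) {
      nn <- neurons[[i]]
      P <- P + nn$touch_counts[sample.int(nrow(nn$touch_counts), m,
                                          replace = TRUE), , drop = FALSE]
    }
    P
  }
  with_seed(seed, {
    perf <- list()
    by_time_last <- NULL
    for (n in n_grid) {
      rms_runs <- numeric(n_boot)
      err_by_t <- matrix(NA_real_, n_boot, nt)
      for (b in seq_len(n_boot)) {
        tr <- pool_draws(n, m_train)
        te <- pool_draws(n, m_test)
        maxc <- max(tr, te) + 1L
        # class-conditional count pmf with add-one smoothing
        logp <- matrix(0, nt, maxc + 1L)
        for (k in seq_len(nt)) {
          tab <- tabulate(tr[, k] + 1L, nbins = maxc + 1L)
          logp[k, ] <- log((tab + 1) / (m_train + maxc + 1L))
        }
        # predict class for each test observation at each true class
        sq <- matrix(NA_real_, m_test, nt)
        for (k in seq_len(nt)) {
          obs <- te[, k] + 1L
          pred <- apply(logp[, obs, drop = FALSE], 2, which.max)
          sq[, k] <- (t_grid[pred] - t_grid[k])^2
        }
        rms_runs[b] <- sqrt(mean(sq))
        err_by_t[b, ] <- sqrt(colMeans(sq))
      }
      perf[[length(perf) + 1L]] <-
        data.frame(n = n, rms_ms = mean(rms_runs),
                   lo = stats::quantile(rms_runs, 0.025, names = FALSE),
                   hi = stats::quantile(rms_runs, 0.975, names = FALSE))
      by_time_last <- data.frame(n = n, t = t_grid,
                                 rms_ms = colMeans(err_by_t))
    }
    structure(list(task = "time", performance = do.call(rbind, perf),
                   by_time = by_time_last),
              class = "decoder_result")
  })
}

#' Cosine phase-response profile of a neuron
#'
#' Expected spikes per whisk cycle in each of \code{n_bins} phase bins
#' for a neuron firing \code{spikes_per_cycle} spikes per cycle on
#' average with cosine tuning of the given modulation depth.
#'
#' @param spikes_per_cycle mean spikes per whisk cycle.
#' @param depth modulation depth in \code{[0, 1]}.
#' @param pref preferred phase (radians).
#' @param n_bins phase bins between \eqn{-\pi} and \eqn{\pi}.
#' @return numeric vector of expected counts per bin (sums to
#'   \code{spikes_per_cycle}).
#' @export
cosine_profile <- function(spikes_per_cycle, depth = 1, pref = 0,
                           n_bins = 120) {
  mid <- seq(-pi, pi, length.out = n_bins + 1L)[-(n_bins + 1L)] + pi / n_bins
  shape <- 1 + depth * cos(mid - pref)
  spikes_per_cycle * shape / sum(shape)
}

#' Phase-response profiles estimated from a session
#'
#' Expected spikes per usable whisk cycle in each phase bin, the
#' empirical analogue of [cosine_profile()].
#'
#' @param spikes,kin spike table and session kinematics.
#' @param n_bins phase bins.
#' @return numeric vector of per-cycle expected counts per bin.
#' @export
phase_profile_from_session <- function(spikes, kin, n_bins = 120) {
  edges <- seq(-pi, pi, length.out = n_bins + 1L)
  counts <- numeric(n_bins)
  n_cyc <- 0L
  for (tid in names(kin)) {
    cyc <- kin[[tid]]$epochs$cycles
    use <- cyc[cyc$phase_ok, , drop = FALSE]
    n_cyc <- n_cyc + nrow(use)
    st <- spikes$time[spikes$trial_id == as.integer(tid)]
    if (!length(st) || nrow(use) == 0L) next
    sp <- spike_phases(st, kin[[tid]]$phase, use)
    good <- !is.na(sp$phase)
    if (any(good)) {
      b <- findInterval(sp$phase[good], edges, rightmost.closed = TRUE)
      b[b > n_bins] <- n_bins
      counts <- counts + tabulate(b, nbins = n_bins)
    }
  }
  if (n_cyc == 0L) stop("no usable whisk cycles")
  counts / n_cyc
}

#' Whisking-phase discrimination by a naive Bayes population decoder
#'
#' Two-class discrimination between phase \eqn{\phi} and
#' \eqn{\phi + \Delta}: the population response is the per-neuron spike
#' count in the probed phase bin of one whisk cycle (Poisson with the
#' profile rate).  Preferred phases are uniformized by random circular
#' shifts of the per-neuron profiles.  For each population size, the
#' smallest \eqn{\Delta} whose percent-correct reaches
#' \code{criterion} (0.76, the two-alternative equivalent of d' = 1) is
#' reported over \code{n_runs} decoding runs.
#'
#' @param profiles list of per-neuron phase profiles (vectors of
#'   expected spikes per cycle per bin, e.g. [cosine_profile()]).
#' @param n_grid population sizes.
#' @param criterion percent-correct criterion.
#' @param n_runs decoding runs (median and 95% band over runs).
#' @param n_test test cycles per class and probe phase.
#' @param n_probe probe phases averaged per run.
#' @param seed RNG seed.
#' @return \code{decoder_result} (task "phase"): \code{performance}
#'   (data frame \code{n}, \code{delta_deg} median resolvable phase
#'   difference, \code{lo}, \code{hi}; \code{NA} when the criterion is
#'   never reached).
#' @export
decode_phase <- function(profiles, n_grid = c(10, 100, 1000),
                         criterion = 0.76, n_runs = 20, n_test = 200,
                         n_probe = 8, seed = NULL) {
  n_bins <- length(profiles[[1]])
  bin_deg <- 360 / n_bins
  with_seed(seed, {
    perf <- list()
    for (n in n_grid) {
      delta_runs <- rep(NA_real_, n_runs)
      for (r in seq_len(n_runs)) {
        ids <- sample.int(length(profiles), n, replace = TRUE)
        shifts <- sample.int(n_bins, n, replace = TRUE) - 1L
        lam <- do.call(rbind, lapply(seq_len(n), function(i) {
          p <- profiles[[ids[i]]]
          s <- shifts[i]
          if (s == 0L) p else c(p[(s + 1):n_bins], p[seq_len(s)])
        }))
        probes <- sample.int(n_bins, n_probe, replace = TRUE)
        for (dlt in seq_len(n_bins %/% 2)) {
          pc <- 0
          for (b0 in probes) {
            b1 <- ((b0 - 1L + dlt) %% n_bins) + 1L
            l0 <- lam[, b0] + 1e-9
            l1 <- lam[, b1] + 1e-9
            wgt <- log(l0 / l1)
            const <- sum(l1 - l0)
            sim_llr <- function(lv) {
              K <- stats::rpois(n_test, sum(lv))
              # each spike contributes the weight of the neuron that fired it
              vapply(K, function(k)
                if (k == 0L) 0 else sum(sample(wgt, k, replace = TRUE,
                                               prob = lv)), numeric(1)) + const
            }
            s0 <- sim_llr(l0)
            s1 <- sim_llr(l1)
            tie_break <- function(s, win_hi) {
              correct <- if (win_hi) s > 0 else s < 0
              correct[s == 0] <- stats::runif(sum(s == 0)) < 0.5
              mean(correct)
            }
            pc <- pc + (tie_break(s0, TRUE) + tie_break(s1, FALSE)) / 2
          }
          pc <- pc / n_probe
          if (pc >= criterion) { delta_runs[r] <- dlt * bin_deg; break }
        }
      }
      known <- delta_runs[!is.na(delta_runs)]
      perf[[length(perf) + 1L]] <- data.frame(
        n = n,
        delta_deg = if (length(known) > n_runs / 2)
          stats::median(known) else NA_real_,
        lo = if (length(known)) min(known) else NA_real_,
        hi = if (length(known) == n_runs)
          stats::quantile(known, 0.975, names = FALSE) else NA_real_,
        frac_resolved = mean(!is.na(delta_runs)))
    }
    structure(list(task = "phase", performance = do.call(rbind, perf)),
              class = "decoder_result")
  })
}

#' @export
print.decoder_result <- function(x, ...) {
  cat(sprintf("decoder_result (%s):\n", x$task))
  print(x$performance, row.names = FALSE)
  invisible(x)
}

#' Convert sensitivity d' to two-alternative proportion correct
#'
#' For the equal-variance Gaussian model of two-alternative
#' discrimination, the proportion correct is \eqn{\Phi(d'/\sqrt{2})}:
#' d' = 1 corresponds to 0.76, d' = 0 to chance.
#'
#' @param d_prime sensitivity (>= 0).
#' @return proportion correct in \code{[0.5, 1)}.
#' @export
dprime_to_pc <- function(d_prime) {
  if (any(d_prime < 0)) stop("d_prime must be >= 0")
  stats::pnorm(d_prime / sqrt(2))
}

#' @rdname dprime_to_pc
#' @param pc proportion correct in \code{[0.5, 1)}.
#' @export
pc_to_dprime <- function(pc) {
  if (any(pc < 0.5 | pc >= 1)) stop("pc must be in [0.5, 1)")
  stats::qnorm(pc) * sqrt(2)
}
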