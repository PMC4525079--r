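#' Event-aligned peri-stimulus time histogram
#'
#' Counts spikes in fixed bins around alignment events and converts to
#' rates (spikes/s).  Alignment events are first-touch onsets, all touch
#' onsets, or trial starts.  The rate in a bin is
#' \code{count / (n_events * bin_width / 1000)}, so
#' \code{sum(rate) * bin_width * n_events / 1000} equals the number of
#' spikes inside the window.
#'
#' @param spikes data frame with \code{trial_id} and \code{time} (ms).
#' @param touches touch table ([extract_touch_features()] output); not
#'   needed for \code{alignment = "trial_start"}.
#' @param alignment one of \code{"all_touch"}, \code{"first_touch"},
#'   \code{"trial_start"}.
#' @param bin_width bin width in ms.
#' @param window length-2 numeric, window around the event in ms
#'   (half-open bins \code{[edge, edge + bin_width)}).
#' @param trial_ids trial ids to use for \code{"trial_start"} alignment
#'   (defaults to the trials present in \code{spikes}).
#' @return object of class \code{psth}: \code{edges}, \code{mid} (bin
#'   starts), \code{count}, \code{rate} (spikes/s), \code{n_events},
#'   \code{bin_width}, \code{alignment}.
#' @export
touch_aligned_psth <- function(spikes, touches = NULL,
                               alignment = c("all_touch", "first_touch",
                                             "trial_start"),
                               bin_width = 1, window = c(-50, 50),
                               trial_ids = NULL) {
  alignment <- match.arg(alignment)
  if (alignment == "trial_start") {
    ids <- trial_ids %||% sort(unique(spikes$trial_id))
    ev <- data.frame(trial_id = ids, onset = 0)
  } else {
    if (is.null(touches) || nrow(touches) == 0L)
      stop("no alignment events")
    ev <- if (alignment == "first_touch")
      touches[touches$is_first, c("trial_id", "onset")]
    else touches[, c("trial_id", "onset")]
  }
  if (nrow(ev) == 0L) stop("no alignment events")
  edges <- seq(window[1], window[2], by = bin_width)
  nb <- length(edges) - 1L
  counts <- numeric(nb)
  for (i in seq_len(nrow(ev))) {
    st <- spikes$time[spikes$trial_id == ev$trial_id[i]] - ev$onset[i]
    st <- st[st >= window[1] & st < window[2]]
    if (length(st))
      counts <- counts + tabulate(findInterval(st, edges), nbins = nb)
  }
  structure(list(edges = edges, mid = edges[-length(edges)], count = counts,
                 rate = counts / (nrow(ev) * bin_width / 1000),
                 n_events = nrow(ev), bin_width = bin_width,
                 alignment = alignment),
            class = "psth")
}

#' @export
print.psth <- function(x, ...) {
  cat(sprintf("psth: %s-aligned, %d events, %g ms bins, peak %.1f spikes/s\n",
              x$alignment, x$n_events, x$bin_width, max(x$rate)))
  invisible(x)
}

#' @export
plot.psth <- function(x, ...) {
  graphics::plot(x$mid + x$bin_width / 2, x$rate, type = "s",
                 xlab = "time from event (ms)", ylab = "rate (spikes/s)", ...)
  graphics::abline(v = 0, lty = 2, col = "grey")
  invisible(x)
}

#' Response onset latency from a touch-aligned PSTH
#'
#' The latency is the start of the first post-onset bin whose rate
#' exceeds the pretouch mean (over -50 to 0 ms) by two pretouch standard
#' deviations.  The bin must contain at least one spike, so that cells
#' with a silent pre-touch baseline (mean and s.d. both 0) still need an
#' actual spike to trigger.  \code{NA} when the threshold is never
#' exceeded within \code{max_latency}.
#'
#' @param psth a [touch_aligned_psth()] with 1 ms bins spanning at least
#'   \code{[-50, max_latency]}.
#' @param max_latency search cap in ms.
#' @return latency in ms, or \code{NA_real_}.
#' @export
onset_latency <- function(psth, max_latency = 50) {
  if (psth$bin_width != 1)
    stop("onset latency requires 1 ms bins")
  if (psth$edges[1] > -50 || psth$edges[length(psth$edges)] < max_latency)
    stop("PSTH window must span [-50, max_latency]")
  pre <- psth$mid >= -50 & psth$mid < 0
  m <- mean(psth$rate[pre])
  s <- stats::sd(psth$rate[pre])
  post <- which(psth$mid >= 0 & psth$mid < max_latency)
  hit <- post[psth$rate[post] > m + 2 * s & psth$count[post] >= 1]
  if (length(hit) == 0L) return(NA_real_)
  psth$mid[hit[1]]
}

# Spike phases by linear interpolation of spike times onto the unwrapped
# phase of the cycle containing each spike.  Returns list(phase, cycle).
spike_phases <- function(spike_times, phase, cycles) {
  out <- rep(NA_real_, length(spike_times))
  cyc_id <- rep(NA_integer_, length(spike_times))
  if (nrow(cycles) == 0L || length(spike_times) == 0L)
    return(list(phase = out, cycle = cyc_id))
  for (k in seq_len(nrow(cycles))) {
    idx <- which(spike_times >= cycles$start[k] & spike_times < cycles$end[k])
    if (!length(idx)) next
    si <- which(phase$t >= cycles$start[k] & phase$t < cycles$end[k])
    if (length(si) < 2L) next
    ph <- phase$phi[si]
    dph <- diff(ph)
    dph[dph < -pi] <- dph[dph < -pi] + 2 * pi
    ph_un <- ph[1] + c(0, cumsum(dph))
    p <- stats::approx(phase$t[si], ph_un, xout = spike_times[idx],
                       rule = 2)$y
    out[idx] <- ((p + pi) %% (2 * pi)) - pi
    cyc_id[idx] <- k
  }
  list(phase = out, cycle = cyc_id)
}

# Weighted cosine fit r(phi) = A [1 + cos(phi - pref)] + B with A, B >= 0.
# Grid over pref with per-grid-point nonnegative least squares, then a
# golden-section refinement around the best grid point.
fit_cosine <- function(phi_mid, rate, w, n_start = 72) {
  sse_at <- function(p0) {
    x <- 1 + cos(phi_mid - p0)
    # weighted LS for rate ~ A x + B, then clamp to A, B >= 0
    sw <- sum(w); sx <- sum(w * x); sy <- sum(w * rate)
    sxx <- sum(w * x^2); sxy <- sum(w * x * rate)
    det <- sw * sxx - sx^2
    if (abs(det) < 1e-12) {
      a <- 0; b <- sy / sw
    } else {
      a <- (sw * sxy - sx * sy) / det
      b <- (sy - a * sx) / sw
    }
    if (a < 0) { a <- 0; b <- sy / sw }
    if (b < 0) { b <- 0; a <- max(0, sxy / sxx) }
    list(sse = sum(w * (rate - a * x - b)^2), A = a, B = b)
  }
  grid <- seq(-pi, pi, length.out = n_start + 1L)[-(n_start + 1L)]
  sses <- vapply(grid, function(g) sse_at(g)$sse, numeric(1))
  best <- grid[which.min(sses)]
  step <- 2 * pi / n_start
  op <- stats::optimize(function(p) sse_at(p)$sse,
                        interval = c(best - step, best + step))
  p0 <- ((op$minimum + pi) %% (2 * pi)) - pi
  c(sse_at(p0), list(pref = p0))
}

#' Cosine phase-tuning fit
#'
#' Builds a 12-bin, occupancy-normalized histogram of firing rate versus
#' whisking phase (spikes per second of time the whisker spends in each
#' phase bin, pooled over usable whisk cycles), and fits
#' \eqn{A[1 + \cos(\phi - \phi_{pref})] + B} with \eqn{A, B \ge 0} by
#' weighted least squares on the binned rates (weights proportional to
#' occupancy; multi-start over a \eqn{\phi_{pref}} grid).  The
#' modulation depth is \eqn{A/(A+B)}.
#'
#' Usable cycles are those flagged \code{phase_ok} by
#' [segment_epochs()]: whisking cycles with monotonic phase, not during
#' licking nor within 70 ms after touch.  Spike phases come from linear
#' interpolation of spike times onto the cycle phase.
#'
#' @param spikes data frame \code{trial_id}, \code{time} for one neuron.
#' @param kin per-trial kinematics: list indexed by trial id with
#'   elements \code{phase} ([decompose_whisking()]) and \code{epochs}
#'   ([segment_epochs()]); see [session_kinematics()].
#' @param n_bins number of phase bins.
#' @return object of class \code{phase_tuning}: \code{A}, \code{B}
#'   (spikes/s), \code{phase_pref} (radians), \code{modulation_depth},
#'   \code{bins} (data frame \code{phi}, \code{rate}, \code{occupancy} s,
#'   \code{count}), \code{n_spikes}, \code{whisking_time} (s).
#' @export
phase_tuning <- function(spikes, kin, n_bins = 12) {
  edges <- seq(-pi, pi, length.out = n_bins + 1L)
  occ <- counts <- numeric(n_bins)
  n_sp <- 0L
  for (tid in names(kin)) {
    ph <- kin[[tid]]$phase
    cyc <- kin[[tid]]$epochs$cycles
    use <- cyc[cyc$phase_ok, , drop = FALSE]
    if (nrow(use) == 0L) next
    keep <- in_iv(ph$t, iv(use$start, use$end))
    if (any(keep)) {
      b <- findInterval(ph$phi[keep], edges, rightmost.closed = TRUE)
      b[b > n_bins] <- n_bins
      occ <- occ + tabulate(b, nbins = n_bins) / 1000  # s per bin
    }
    st <- spikes$time[spikes$trial_id == as.integer(tid)]
    if (!length(st)) next
    sp <- spike_phases(st, ph, use)
    good <- !is.na(sp$phase)
    n_sp <- n_sp + sum(good)
    if (any(good)) {
      b <- findInterval(sp$phase[good], edges, rightmost.closed = TRUE)
      b[b > n_bins] <- n_bins
      counts <- counts + tabulate(b, nbins = n_bins)
    }
  }
  if (sum(occ) == 0) stop("no usable whisking time for phase tuning")
  rate <- ifelse(occ > 0, counts / occ, 0)
  mid <- edges[-length(edges)] + diff(edges) / 2
  if (n_sp == 0L) {
    warning("no spikes during usable whisking cycles; depth undefined")
    fit <- list(A = 0, B = 0, pref = NA_real_)
    depth <- NA_real_
  } else {
    fit <- fit_cosine(mid, rate, w = pmax(occ, 1e-12))
    depth <- if (fit$A + fit$B > 0) fit$A / (fit$A + fit$B) else NA_real_
  }
  structure(list(A = fit$A, B = fit$B, phase_pref = fit$pref,
                 modulation_depth = depth,
                 bins = data.frame(phi = mid, rate = rate, occupancy = occ,
                                   count = counts),
                 n_spikes = n_sp, whisking_time = sum(occ)),
            class = "phase_tuning")
}

#' @export
print.phase_tuning <- function(x, ...) {
  cat(sprintf(paste0("phase_tuning: A = %.3f, B = %.3f spikes/s, pref = %.2f",
                     " rad, depth = %.3f (%d spikes, %.1f s whisking)\n"),
              x$A, x$B, x$phase_pref, x$modulation_depth, x$n_spikes,
              x$whisking_time))
  invisible(x)
}

#' Spike counts per touch in a fixed window
#'
#' @param spikes data frame \code{trial_id}, \code{time}.
#' @param touches touch table.
#' @param window length-2 offsets (ms) relative to touch onset, half-open.
#' @return integer vector, one count per row of \code{touches}.
#' @export
touch_spike_counts <- function(spikes, touches, window) {
  vapply(seq_len(nrow(touches)), function(i) {
    st <- spikes$time[spikes$trial_id == touches$trial_id[i]]
    sum(st >= touches$onset[i] + window[1] & st < touches$onset[i] + window[2])
  }, numeric(1))
}

#' Epoch firing rates and interspike-interval summary
#'
#' Firing rate inside each epoch class (spike count divided by the total
#' class duration), the minimum interspike interval over the session,
#' and optionally spike counts per touch in a response window.
#'
#' @param spikes data frame \code{trial_id}, \code{time}.
#' @param kin per-trial kinematics (see [phase_tuning()]).
#' @param touches optional touch table for per-touch counts.
#' @param window response window \code{c(lo, hi)} in ms relative to touch
#'   onset; defaults to \code{[latency, latency + 30)} with
#'   \code{latency = 8} when touches are supplied.
#' @return list: \code{whisking_rate}, \code{non_whisking_rate}
#'   (spikes/s; \code{NA} when an epoch class has zero duration),
#'   \code{min_isi} (ms; \code{NA} for < 2 spikes in every trial),
#'   \code{spikes_per_touch} (vector or NULL).
#' @export
epoch_rates <- function(spikes, kin, touches = NULL, window = NULL) {
  wdur <- ndur <- 0
  wcount <- ncount <- 0L
  isis <- numeric(0)
  for (tid in names(kin)) {
    ep <- kin[[tid]]$epochs
    st <- spikes$time[spikes$trial_id == as.integer(tid)]
    wdur <- wdur + iv_duration(ep$whisking)
    ndur <- ndur + iv_duration(ep$non_whisking)
    if (length(st)) {
      wcount <- wcount + sum(in_iv(st, ep$whisking))
      ncount <- ncount + sum(in_iv(st, ep$non_whisking))
      if (length(st) > 1L) isis <- c(isis, diff(sort(st)))
    }
  }
  if (wdur == 0) warning("zero whisking duration; whisking rate undefined")
  if (ndur == 0) warning("zero non-whisking duration; non-whisking rate undefined")
  spt <- NULL
  if (!is.null(touches) && nrow(touches)) {
    if (is.null(window)) window <- c(8, 38)
    spt <- touch_spike_counts(spikes, touches, window)
  }
  list(whisking_rate = if (wdur > 0) 1000 * wcount / wdur else NA_real_,
       non_whisking_rate = if (ndur > 0) 1000 * ncount / ndur else NA_real_,
       min_isi = if (length(isis)) min(isis) else NA_real_,
       spikes_per_touch = spt)
}

#' Run kinematic decomposition for every trial of a session
#'
#' Convenience wrapper producing the per-trial kinematics container used
#' by the analysis functions: for each trial, the phase decomposition,
#' the epoch segmentation and the touch features.
#'
#' @param session a [generate_session()] or [read_session()] object.
#' @param ... passed to [segment_epochs()].
#' @return named list (by trial id as character) of lists with elements
#'   \code{phase}, \code{epochs}, \code{touches}.
#' @export
session_kinematics <- function(session, ...) {
  out <- list()
  for (tr in session$traces) {
    ph <- decompose_whisking(tr)
    out[[as.character(tr$trial_id)]] <-
      list(phase = ph, epochs = segment_epochs(tr, ph, ...),
           touches = extract_touch_features(tr))
  }
  out
}
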