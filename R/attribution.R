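# Spike attribution to touch onset and whisking phase.
#
# The attribution logic works on cumulative "explained spikes" curves: for
# an expanding window around the candidate event (touch onset shifted by
# the cell's latency, or the preferred-phase time of each whisk cycle),
# y(t) counts the spikes falling inside the window.  The window stops
# growing at the first step whose increment drops below the chance slope,
# estimated from spike-time shuffles redistributed uniformly over the
# same epochs (cumulative surrogate curves smoothed with a degree-11
# polynomial before differentiation; 95th percentile of the slopes).

# Smoothed per-ms slopes of cumulative curves (grid 0..t_max, first row 0).
surrogate_slopes <- function(Y, degree = 11) {
  g <- seq_len(nrow(Y)) - 1L
  xs <- 2 * g / max(g) - 1  # scale to [-1, 1] for numerical stability
  Q <- cbind(1, stats::poly(xs, degree = degree))
  S <- Q %*% qr.coef(qr(Q), Y)
  diff(S)
}

# Cumulative spike-count curve over 1 ms expanding windows.
# u: per-spike distances (>= 0, Inf when unattributable).
cum_curve <- function(u, t_max) {
  b <- floor(u[is.finite(u) & u >= 0 & u < t_max]) + 1L
  cumsum(tabulate(b, nbins = t_max))
}

#' Fraction of exploration spikes coupled to touch onset
#'
#' Each spike falling in an exploration epoch is indexed by the time
#' elapsed since the most recent touch onset of its trial, minus the
#' cell's response latency.  The cumulative curve \code{y(t)} counts
#' spikes within \code{t} ms of (shifted) touch onset for an expanding
#' window \code{t = 1..t_max}.  Chance is estimated by redistributing
#' the exploration spikes uniformly within the exploration epochs
#' (\code{n_shuffle} times), smoothing each surrogate cumulative curve
#' with a degree-11 polynomial, and taking the 95th percentile of the
#' surrogate slopes at each window size.  The empirical curve receives
#' the same smoothing before differentiation; the touch window cutoff
#' \code{t_on} is the first step whose smoothed empirical slope falls
#' below the chance slope.  The touch-coupled fraction is
#' \code{y(t_on)} divided by the number of exploration spikes.
#'
#' @param spikes data frame \code{trial_id}, \code{time}.
#' @param kin per-trial kinematics from [session_kinematics()].
#' @param latency response latency in ms (from [onset_latency()]).
#' @param t_max largest window size probed (ms).
#' @param n_shuffle number of spike-time shuffles.
#' @param seed RNG seed for the shuffles.
#' @return object of class \code{attribution_curves}: \code{t} (1..t_max),
#'   \code{y}, \code{dy}, \code{chance_slope}, surrogate cumulative
#'   quantiles \code{y_null_q95}/\code{y_null_mean}, \code{t_on},
#'   \code{frac_touch}, \code{occupancy_touch} (fraction of exploration
#'   time inside the touch windows), \code{n_exploration_spikes},
#'   \code{attributed} (row indices into \code{spikes}),
#'   \code{exploration_rows}.
#' @export
touch_coupled_fraction <- function(spikes, kin, latency, t_max = 100,
                                   n_shuffle = 1000, seed = NULL) {
  if (is.na(latency)) latency <- 0
  u_all <- numeric(0)           # per exploration spike: time since onset - latency
  expl_rows <- integer(0)
  null_bins <- NULL             # per-shuffle tabulated distances
  occ_iv_time <- 0
  expl_time <- 0
  with_seed(seed, {
    shuffle_u <- vector("list", length(kin))
    ki <- 0L
    for (tid in names(kin)) {
      ki <- ki + 1L
      ep <- kin[[tid]]$epochs
      expl <- ep$exploration
      expl_time <- expl_time + iv_duration(expl)
      rows <- which(spikes$trial_id == as.integer(tid))
      rows <- rows[in_iv(spikes$time[rows], expl)]
      if (!length(rows)) next
      expl_rows <- c(expl_rows, rows)
      onsets <- sort(kin[[tid]]$touches$onset)
      time_since_onset <- function(ts) {
        val <- rep(Inf, length(ts))
        if (length(onsets)) {
          k <- findInterval(ts, onsets)
          pos <- k > 0
          val[pos] <- ts[pos] - onsets[k[pos]] - latency
        }
        val[val < 0] <- Inf  # spikes before onset + latency: not attributable
        val
      }
      st <- spikes$time[rows]
      u_all <- c(u_all, time_since_onset(st))
      # shuffles: same per-trial spike count, uniform over exploration
      if (n_shuffle > 0) {
        sh_t <- runif_iv(length(st) * n_shuffle, expl)
        su <- time_since_onset(sh_t)
        ok <- is.finite(su) & su < t_max
        bin <- floor(su[ok]) + 1L +
          t_max * (rep(seq_len(n_shuffle), each = length(st))[ok] - 1L)
        shuffle_u[[ki]] <- tabulate(bin, nbins = t_max * n_shuffle)
      }
    }
    n_expl <- length(u_all)
    tgrid <- seq_len(t_max)
    if (n_expl == 0L) {
      warning("no exploration spikes; touch attribution undefined")
      return(structure(list(t = tgrid, y = rep(0L, t_max),
                            dy = rep(0L, t_max), dy_smooth = rep(NA, t_max),
                            chance_slope = rep(NA, t_max),
                            y_null_q95 = rep(NA, t_max),
                            y_null_mean = rep(NA, t_max),
                            t_on = NA_real_, latency = latency,
                            frac_touch = NA_real_, occupancy_touch = NA_real_,
                            n_exploration_spikes = 0L,
                            attributed = integer(0),
                            exploration_rows = integer(0)),
                       class = "attribution_curves"))
    }
    y <- cum_curve(u_all, t_max)
    dy <- diff(c(0L, y))
    # empirical and surrogate curves get the same polynomial smoothing
    # before differentiation, so the cutoff compares like with like
    dy_s <- drop(surrogate_slopes(matrix(c(0, y), ncol = 1)))
    cnt <- Reduce(`+`, Filter(Negate(is.null), shuffle_u))
    if (is.null(cnt)) cnt <- integer(t_max * n_shuffle)
    cntm <- matrix(cnt, nrow = t_max)
    Y <- apply(cntm, 2, cumsum)
    slopes <- surrogate_slopes(rbind(0, Y))
    chance <- apply(slopes, 1, stats::quantile, probs = 0.95, names = FALSE)
    hit <- which(dy_s < chance)
    t_on <- if (length(hit)) tgrid[hit[1]] else t_max
    frac <- y[t_on] / n_expl
    # occupancy of the touch windows within exploration
    for (tid in names(kin)) {
      onsets <- kin[[tid]]$touches$onset
      if (!length(onsets)) next
      win <- iv_union(iv(onsets + latency, onsets + latency + t_on))
      occ_iv_time <- occ_iv_time +
        iv_duration(iv_intersect(win, kin[[tid]]$epochs$exploration))
    }
    structure(list(t = tgrid, y = y, dy = dy, chance_slope = chance,
                   y_null_q95 = apply(Y, 1, stats::quantile, probs = 0.95,
                                      names = FALSE),
                   y_null_mean = rowMeans(Y),
                   dy_smooth = dy_s,
                   t_on = t_on, latency = latency, frac_touch = frac,
                   occupancy_touch = if (expl_time > 0)
                     occ_iv_time / expl_time else NA_real_,
                   n_exploration_spikes = n_expl,
                   attributed = expl_rows[is.finite(u_all) & u_all >= 0 &
                                            u_all < t_on],
                   exploration_rows = expl_rows),
              class = "attribution_curves")
  })
}

#' @export
print.attribution_curves <- function(x, ...) {
  cat(sprintf(paste0("attribution_curves: %d exploration spikes, t_on = %s ms",
                     " after latency %.0f ms, frac_touch = %.3f",
                     " (occupancy %.3f)\n"),
              x$n_exploration_spikes, format(x$t_on), x$latency,
              x$frac_touch, x$occupancy_touch))
  invisible(x)
}

# Preferred-phase crossing times within one cycle (possibly several for
# non-monotonic phase).
pref_crossings <- function(phase, start, end, phase_pref) {
  si <- which(phase$t >= start & phase$t < end)
  if (length(si) < 2L) return(numeric(0))
  ph <- phase$phi[si]
  dph <- diff(ph)
  dph[dph < -pi] <- dph[dph < -pi] + 2 * pi
  ph_un <- ph[1] + c(0, cumsum(dph))
  lo <- min(ph_un); hi <- max(ph_un)
  ks <- ceiling((lo - phase_pref) / (2 * pi)):floor((hi - phase_pref) / (2 * pi))
  out <- numeric(0)
  for (k in ks) {
    target <- phase_pref + 2 * pi * k
    s <- ph_un - target
    cross <- which(s[-length(s)] * s[-1] <= 0 & (s[-length(s)] != s[-1]))
    for (j in cross) {
      frac <- s[j] / (s[j] - s[j + 1])
      out <- c(out, phase$t[si[j]] + frac)
    }
    if (any(s == 0)) out <- c(out, phase$t[si[s == 0]])
  }
  sort(unique(out))
}

#' Fraction of spikes coupled to touch or whisking phase
#'
#' Takes the residual exploration spikes (those not attributed to touch
#' by [touch_coupled_fraction()]) and indexes each spike inside a whisk
#' cycle by its absolute time to the nearest preferred-phase crossing of
#' that cycle (windows are truncated at cycle margins; non-monotonic
#' cycles contribute all their crossings).  The same expanding-window /
#' shuffle-chance rule yields the phase window cutoff \code{t_w}.  The
#' combined fraction adds the windowed residual spikes to the
#' touch-attributed spikes.
#'
#' @param att output of [touch_coupled_fraction()].
#' @param spikes the same spike table passed to the touch step.
#' @param kin per-trial kinematics from [session_kinematics()].
#' @param phase_pref preferred phase (radians), e.g. from
#'   [phase_tuning()].
#' @param t_max largest half-window probed (ms).
#' @param n_shuffle,seed chance-curve controls.
#' @return object of class \code{attribution_result}: \code{frac_touch},
#'   \code{frac_touch_or_phase}, \code{frac_phase_only}, \code{t_on},
#'   \code{t_w}, \code{occupancy_touch}, \code{occupancy_total},
#'   and the phase curves (\code{t}, \code{y_whisk},
#'   \code{chance_slope}).
#' @export
phase_coupled_fraction <- function(att, spikes, kin, phase_pref,
                                   t_max = 50, n_shuffle = 1000, seed = NULL) {
  resid_rows <- setdiff(att$exploration_rows, att$attributed)
  n_expl <- att$n_exploration_spikes
  tgrid <- seq_len(t_max)
  empty <- function(frac_both) {
    structure(list(frac_touch = att$frac_touch,
                   frac_touch_or_phase = frac_both,
                   frac_phase_only = frac_both - att$frac_touch,
                   t_on = att$t_on, t_w = NA_real_,
                   occupancy_touch = att$occupancy_touch,
                   occupancy_total = att$occupancy_touch,
                   t = tgrid, y_whisk = rep(0L, t_max),
                   chance_slope = rep(NA_real_, t_max)),
              class = "attribution_result")
  }
  if (is.na(att$frac_touch)) return(empty(NA_real_))
  with_seed(seed, {
    d_all <- numeric(0)
    null_tab <- NULL
    cyc_by_trial <- list()
    for (tid in names(kin)) {
      cyc <- kin[[tid]]$epochs$cycles
      cyc <- cyc[cyc$p2p > 2.5, , drop = FALSE]
      cyc_by_trial[[tid]] <- cyc
      rows <- resid_rows[spikes$trial_id[resid_rows] == as.integer(tid)]
      support <- iv_intersect(if (nrow(cyc)) iv(cyc$start, cyc$end)
                              else iv_empty(),
                              kin[[tid]]$epochs$exploration)
      if (nrow(cyc) == 0L || nrow(support) == 0L) next
      crossings <- lapply(seq_len(nrow(cyc)), function(k)
        pref_crossings(kin[[tid]]$phase, cyc$start[k], cyc$end[k], phase_pref))
      dist_to_pref <- function(ts) {
        d <- rep(Inf, length(ts))
        if (!length(ts)) return(d)
        ci <- findInterval(ts, as.vector(t(as.matrix(cyc[, c("start", "end")]))))
        inside <- ci %% 2L == 1L
        for (ii in which(inside)) {
          k <- (ci[ii] + 1L) %/% 2L
          if (length(crossings[[k]]))
            d[ii] <- min(abs(ts[ii] - crossings[[k]]))
        }
        d
      }
      st <- spikes$time[rows]
      st_in <- in_iv(st, support)
      d_all <- c(d_all, dist_to_pref(st[st_in]))
      n_in <- sum(st_in)
      if (n_in > 0 && n_shuffle > 0) {
        sh <- runif_iv(n_in * n_shuffle, support)
        sd_ <- dist_to_pref(sh)
        ok <- is.finite(sd_) & sd_ < t_max
        bin <- floor(sd_[ok]) + 1L +
          t_max * (rep(seq_len(n_shuffle), each = n_in)[ok] - 1L)
        tb <- tabulate(bin, nbins = t_max * n_shuffle)
        null_tab <- if (is.null(null_tab)) tb else null_tab + tb
      }
    }
    if (length(d_all) == 0L) return(empty(att$frac_touch))
    y <- cum_curve(d_all, t_max)
    dy_s <- drop(surrogate_slopes(matrix(c(0, y), ncol = 1)))
    cntm <- matrix(null_tab %||% integer(t_max * n_shuffle), nrow = t_max)
    Y <- apply(cntm, 2, cumsum)
    slopes <- surrogate_slopes(rbind(0, Y))
    chance <- apply(slopes, 1, stats::quantile, probs = 0.95, names = FALSE)
    hit <- which(dy_s < chance)
    t_w <- if (length(hit)) tgrid[hit[1]] else t_max
    n_phase <- y[t_w]
    frac_both <- (att$frac_touch * n_expl + n_phase) / n_expl
    # occupancy: phase windows truncated at cycle margins, touch windows
    # removed to avoid double counting
    occ <- 0; expl_time <- 0
    for (tid in names(kin)) {
      ep <- kin[[tid]]$epochs
      expl_time <- expl_time + iv_duration(ep$exploration)
      cyc <- cyc_by_trial[[tid]]
      if (is.null(cyc) || nrow(cyc) == 0L) next
      wins <- iv_empty()
      for (k in seq_len(nrow(cyc))) {
        cr <- pref_crossings(kin[[tid]]$phase, cyc$start[k], cyc$end[k],
                             phase_pref)
        if (!length(cr)) next
        w <- iv_intersect(iv_union(iv(cr - t_w, cr + t_w)),
                          iv(cyc$start[k], cyc$end[k]))
        wins <- rbind(wins, w)
      }
      wins <- iv_intersect(iv_union(wins), ep$exploration)
      onsets <- kin[[tid]]$touches$onset
      if (length(onsets))
        wins <- iv_setdiff(wins, iv(onsets + att$latency,
                                    onsets + att$latency + att$t_on))
      occ <- occ + iv_duration(wins)
    }
    structure(list(frac_touch = att$frac_touch,
                   frac_touch_or_phase = frac_both,
                   frac_phase_only = frac_both - att$frac_touch,
                   t_on = att$t_on, t_w = t_w,
                   occupancy_touch = att$occupancy_touch,
                   occupancy_total = att$occupancy_touch +
                     if (expl_time > 0) occ / expl_time else 0,
                   t = tgrid, y_whisk = y, chance_slope = chance),
              class = "attribution_result")
  })
}

#' @export
print.attribution_result <- function(x, ...) {
  cat(sprintf(paste0("attribution_result: touch %.1f%%, touch+phase %.1f%%",
                     " (windows t_on = %s, t_w = %s ms; occupancy %.1f%%)\n"),
              100 * x$frac_touch, 100 * x$frac_touch_or_phase,
              format(x$t_on), format(x$t_w), 100 * x$occupancy_total))
  invisible(x)
}
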