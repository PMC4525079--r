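# Spike-count variability analysis: Fano factors, the binomial minimum
# bound, inter-contact-interval touch selection, density-based grouping of
# touches by stimulus features (OPTICS ordering + consecutive-window scan),
# sliding-window Fano curves, refractory-Poisson null simulations, and the
# five-condition alignment comparison.

#' Fano factor of a set of spike counts
#'
#' Variance divided by mean.  The population (biased, 1/n) variance is
#' the default, matching common usage in the spike-count variability
#' literature; the sample (1/(n-1)) estimator is available.
#'
#' @param counts integer vector of spike counts (>= 2 values).
#' @param estimator \code{"population"} or \code{"sample"} variance.
#' @return variance/mean; \code{NA} (with a warning) when the mean is 0.
#' @export
fano_factor <- function(counts, estimator = c("population", "sample")) {
  estimator <- match.arg(estimator)
  if (length(counts) < 2L) stop("need at least 2 counts")
  m <- mean(counts)
  if (m == 0) {
    warning("mean count is zero; Fano factor undefined")
    return(NA_real_)
  }
  v <- if (estimator == "population") mean((counts - m)^2) else stats::var(counts)
  v / m
}

#' Minimum Fano factor for integer counts at a fixed mean
#'
#' Spike counts are whole numbers, so for a non-integer mean the
#' variance cannot be zero.  The minimum-variance distribution puts all
#' mass on the two integers bracketing the mean, giving
#' \eqn{FF_{min}(\mu) = (\mu - k)(k + 1 - \mu)/\mu} with
#' \eqn{k = \lfloor \mu \rfloor}; for \eqn{\mu < 1} this reduces to
#' \eqn{1 - \mu} (binomial 0/1 spiking), and it is 0 at integer means.
#'
#' @param mean numeric vector of mean spike counts (>= 0).
#' @return minimum Fano factor, \code{NaN} at mean 0.
#' @export
min_fano <- function(mean) {
  if (any(mean < 0)) stop("mean must be non-negative")
  k <- floor(mean)
  ifelse(mean == 0, NaN, (mean - k) * (k + 1 - mean) / mean)
}

#' Brute-force minimum Fano factor over integer-supported distributions
#'
#' Minimizes variance/mean over all probability distributions supported
#' on \code{0..max_count} with the given mean.  Since variance is linear
#' in the probabilities with two linear equality constraints, the
#' optimum is attained at a basic feasible solution with at most two
#' support points; all support pairs are enumerated exactly.
#'
#' @param mean target mean (0 < mean <= max_count).
#' @param max_count largest count in the support.
#' @return list: \code{ff} (the minimized Fano factor), \code{support}
#'   and \code{prob} of the achieving distribution.
#' @export
min_fano_brute <- function(mean, max_count = 5) {
  if (mean <= 0 || mean > max_count) stop("mean must be in (0, max_count]")
  supp <- 0:max_count
  best <- list(ff = Inf, support = NULL, prob = NULL)
  for (a in supp) {
    if (a == mean) {  # degenerate single-point solution
      if (0 < best$ff) best <- list(ff = 0, support = a, prob = 1)
      next
    }
    for (b in supp[supp > a]) {
      # p on b, 1-p on a with a*(1-p) + b*p = mean
      p <- (mean - a) / (b - a)
      if (p < 0 || p > 1) next
      v <- (1 - p) * a^2 + p * b^2 - mean^2
      if (v / mean < best$ff)
        best <- list(ff = v / mean, support = c(a, b), prob = c(1 - p, p))
    }
  }
  best
}

#' Select touches preceded by a long inter-contact interval
#'
#' Keeps touches whose inter-contact interval (time since the previous
#' touch offset) is strictly greater than \code{min_ici} ms.  First
#' touches of a trial (\code{ici = Inf}) always pass.
#'
#' @param touches touch table with an \code{ici} column.
#' @param min_ici threshold in ms.
#' @return filtered touch table.
#' @export
select_touches <- function(touches, min_ici = 250) {
  touches[touches$ici > min_ici, , drop = FALSE]
}

#' OPTICS ordering of points by density reachability
#'
#' Standard OPTICS: the core distance of a point is its distance to the
#' \code{min_pts}-th nearest neighbour (the point itself included); the
#' algorithm repeatedly emits the unprocessed point with the smallest
#' reachability distance and relaxes the reachability of its
#' neighbours.  With unlimited \code{eps} every point is emitted, so the
#' result is a density-based ordering in which similar points are
#' adjacent.
#'
#' @param x numeric matrix of points (rows) x features (columns).
#' @param min_pts neighbourhood size defining the core distance.
#' @param eps maximum reachability radius (\code{Inf} = unlimited).
#' @return list: \code{order} (point indices in output order),
#'   \code{reachability} (aligned with \code{order}; \code{Inf} for the
#'   first point of each component), \code{core_distance}.
#' @export
optics_order <- function(x, min_pts = 10, eps = Inf) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < min_pts) stop("fewer points than min_pts")
  D <- as.matrix(stats::dist(x))
  core <- apply(D, 1, function(d) sort(d, partial = min_pts)[min_pts])
  seen <- logical(n)
  reach <- rep(Inf, n)
  ord <- integer(n)
  in_seeds <- logical(n)
  for (pos in seq_len(n)) {
    cand <- which(in_seeds & !seen)
    i <- if (length(cand) && any(is.finite(reach[cand]))) {
      cand[which.min(reach[cand])]
    } else {
      which(!seen)[1]   # start a new component
    }
    seen[i] <- TRUE
    in_seeds[i] <- FALSE
    ord[pos] <- i
    if (core[i] <= eps) {
      newreach <- pmax(core[i], D[i, ])
      upd <- !seen & newreach < reach & D[i, ] <= eps
      reach[upd] <- newreach[upd]
      in_seeds[upd] <- TRUE
    }
  }
  list(order = ord, reachability = reach[ord], core_distance = core)
}

# Sum of pairwise distances inside each window of N consecutive ordered
# points; returns the start index of the minimizing window.
best_window <- function(D, ord, N) {
  n <- length(ord)
  Do <- D[ord, ord, drop = FALSE]
  w <- seq_len(N)
  S <- sum(Do[w, w]) / 2
  best_s <- S
  best_i <- 1L
  if (n > N) {
    for (i in 2:(n - N + 1L)) {
      out <- i - 1L
      rest <- i:(i + N - 2L)
      S <- S - sum(Do[out, rest]) + sum(Do[i + N - 1L, rest])
      if (S < best_s) { best_s <- S; best_i <- i }
    }
  }
  best_i
}

#' Group touches by stimulus similarity
#'
#' Z-scores the touch features (pretouch velocity and maximum curvature
#' change by default), then extracts \code{n_groups} groups of similar
#' touches iteratively: run OPTICS on the remaining touches, scan all
#' windows of \code{N} consecutive points in the OPTICS order, take the
#' window minimizing the total pairwise Euclidean distance as the next
#' group, remove it, and repeat.  \code{N} is 20% of the remaining
#' touches, floored at \code{min_size}.
#'
#' @param features numeric matrix or data frame, touches x features.
#' @param n_groups number of groups.
#' @param min_size minimum touches per group.
#' @param frac window size as a fraction of the remaining touches.
#' @param min_pts OPTICS neighbourhood size.
#' @return object of class \code{touch_grouping}: \code{groups} (list of
#'   row-index vectors), \code{assignment} (integer per touch, \code{NA}
#'   if left ungrouped), \code{group_sd} (mean per-feature s.d. within
#'   each group), \code{features_z}.
#' @export
group_touches <- function(features, n_groups = 5, min_size = 20, frac = 0.2,
                          min_pts = 10) {
  X <- scale(as.matrix(features))
  X[is.nan(X)] <- 0   # constant feature: zero contribution to distances
  n <- nrow(X)
  if (n < n_groups * min_size)
    stop(sprintf("need at least %d touches (%d groups x %d), got %d",
                 n_groups * min_size, n_groups, min_size, n))
  remaining <- seq_len(n)
  groups <- vector("list", n_groups)
  assignment <- rep(NA_integer_, n)
  for (g in seq_len(n_groups)) {
    nr <- length(remaining)
    N <- min(nr, max(min_size, ceiling(frac * nr)))
    Xr <- X[remaining, , drop = FALSE]
    op <- optics_order(Xr, min_pts = min(min_pts, nr))
    D <- as.matrix(stats::dist(Xr))
    i <- best_window(D, op$order, N)
    sel <- op$order[i:(i + N - 1L)]
    groups[[g]] <- remaining[sel]
    assignment[remaining[sel]] <- g
    remaining <- remaining[-sel]
  }
  group_sd <- vapply(groups, function(ii)
    mean(apply(X[ii, , drop = FALSE], 2, stats::sd)), numeric(1))
  structure(list(groups = groups, assignment = assignment,
                 group_sd = group_sd, features_z = X),
            class = "touch_grouping")
}

#' @export
print.touch_grouping <- function(x, ...) {
  cat(sprintf("touch_grouping: %d groups, sizes %s, mean within-group sd %s\n",
              length(x$groups),
              paste(lengths(x$groups), collapse = "/"),
              paste(sprintf("%.2f", x$group_sd), collapse = "/")))
  invisible(x)
}

# FF with bootstrap CI for one count vector; NA-safe for zero mean.
ff_boot <- function(counts, n_boot, estimator) {
  m <- mean(counts)
  if (m == 0 || length(counts) < 2L)
    return(c(ff = NA_real_, lo = NA_real_, hi = NA_real_, mean = m))
  ff <- fano_factor(counts, estimator)
  bs <- replicate(n_boot, {
    x <- counts[sample.int(length(counts), replace = TRUE)]
    if (mean(x) == 0) NA_real_ else
      suppressWarnings(fano_factor(x, estimator))
  })
  qs <- stats::quantile(bs, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  c(ff = ff, lo = qs[1], hi = qs[2], mean = m)
}

#' Sliding-window Fano factor around touch onset
#'
#' For every offset, counts spikes in \code{[onset + offset,
#' onset + offset + window)} across touches and computes the Fano
#' factor, its bootstrap 95% CI, and the binomial minimum bound
#' [min_fano()] at the observed mean count.  With a
#' [group_touches()] grouping, curves are computed per group; group 0
#' denotes the pooled curve over all supplied touches.
#'
#' @param spikes data frame \code{trial_id}, \code{time}.
#' @param touches touch table (typically after [select_touches()]).
#' @param grouping optional [group_touches()] result aligned with
#'   \code{touches} rows.
#' @param window window length in ms.
#' @param offsets vector of window start offsets (ms after onset).
#' @param n_boot bootstrap resamples.
#' @param seed RNG seed.
#' @param estimator variance estimator, see [fano_factor()].
#' @return object of class \code{fano_curve}: data frame \code{curve}
#'   (\code{group}, \code{offset}, \code{mean_count}, \code{ff},
#'   \code{lo}, \code{hi}, \code{binomial_min}), \code{min_ff} (named
#'   vector: minimum FF over offsets per group), \code{min_ff_overall}
#'   (minimum over the per-group minima, excluding the pooled curve when
#'   groups exist), \code{window}, \code{offsets}.
#' @export
sliding_fano <- function(spikes, touches, grouping = NULL, window = 10,
                         offsets = 0:20, n_boot = 1000, seed = NULL,
                         estimator = "population") {
  groups <- list(`0` = seq_len(nrow(touches)))
  if (!is.null(grouping)) {
    gl <- grouping$groups
    names(gl) <- as.character(seq_along(gl))
    groups <- c(groups, gl)
  }
  counts_at <- function(off)
    touch_spike_counts(spikes, touches, c(off, off + window))
  with_seed(seed, {
    all_counts <- lapply(offsets, counts_at)
    rows <- list()
    for (gi in seq_along(groups)) {
      gname <- names(groups)[gi]
      idx <- groups[[gi]]
      if (length(idx) < 2L) {
        warning("group ", gname, " has fewer than 2 touches; skipped")
        next
      }
      for (oi in seq_along(offsets)) {
        x <- all_counts[[oi]][idx]
        fb <- ff_boot(x, n_boot, estimator)
        rows[[length(rows) + 1L]] <-
          data.frame(group = as.integer(gname), offset = offsets[oi],
                     mean_count = fb["mean"], ff = fb["ff"],
                     lo = fb["lo"], hi = fb["hi"],
                     binomial_min = if (fb["mean"] > 0)
                       min_fano(fb["mean"]) else NA_real_)
      }
    }
    curve <- do.call(rbind, rows)
    rownames(curve) <- NULL
    min_ff <- tapply(curve$ff, curve$group, function(v)
      if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE))
    grp_ids <- setdiff(names(min_ff), if (length(groups) > 1L) "0" else character(0))
    overall <- suppressWarnings(min(unlist(min_ff[grp_ids]), na.rm = TRUE))
    structure(list(curve = curve, min_ff = min_ff,
                   min_ff_overall = if (is.finite(overall)) overall else NA_real_,
                   window = window, offsets = offsets),
              class = "fano_curve")
  })
}

#' @export
print.fano_curve <- function(x, ...) {
  cat(sprintf("fano_curve: %g ms window, offsets %g..%g ms, min FF %.3f\n",
              x$window, min(x$offsets), max(x$offsets), x$min_ff_overall))
  invisible(x)
}

#' @export
plot.fano_curve <- function(x, group = 0, ...) {
  cv <- x$curve[x$curve$group == group, ]
  graphics::plot(cv$offset, cv$ff, type = "b", ylim = c(0, max(cv$hi, 1.2,
                 na.rm = TRUE)), xlab = "window offset (ms)",
                 ylab = "Fano factor", ...)
  graphics::lines(cv$offset, cv$binomial_min, col = "darkgreen")
  graphics::abline(h = 1, lty = 2, col = "grey")
  invisible(x)
}

#' Fano curve of a refractory Poisson null matched to a response profile
#'
#' Simulates an inhomogeneous Poisson process whose rate follows the
#' PSTH (the average touch response), deletes spikes arriving within the
#' refractory period of the previous spike (forward deletion), and
#' returns the same sliding-window Fano curve for comparison with the
#' data.  With refractory 0 this is a plain Poisson process and the FF
#' is 1 up to Monte-Carlo error at every offset.
#'
#' @param psth a [touch_aligned_psth()] with 1 ms bins (rate profile).
#' @param refractory absolute refractory period (ms).
#' @param n_events number of simulated events (trials).
#' @param seed RNG seed.
#' @param window,offsets sliding-window parameters as in
#'   [sliding_fano()].
#' @param n_boot bootstrap resamples for the CI.
#' @return a \code{fano_curve} (single pooled group).
#' @export
refractory_poisson_null <- function(psth, refractory, n_events = 1000,
                                    seed = NULL, window = 10, offsets = 0:20,
                                    n_boot = 1000) {
  if (refractory < 0) stop("refractory must be >= 0")
  stopifnot(psth$bin_width == 1)
  with_seed(seed, {
    lam <- psth$rate / 1000  # spikes per 1 ms bin
    nb <- length(lam)
    sim_counts <- matrix(0L, nrow = n_events, ncol = length(offsets))
    for (ev in seq_len(n_events)) {
      k <- stats::rpois(nb, lam)
      if (sum(k) == 0L) next
      ts <- sort(rep(psth$mid, k) + stats::runif(sum(k)))
      if (refractory > 0 && length(ts) > 1L) {
        keep <- rep(TRUE, length(ts))
        last <- ts[1]
        for (i in 2:length(ts)) {
          if (ts[i] - last < refractory) keep[i] <- FALSE else last <- ts[i]
        }
        ts <- ts[keep]
      }
      for (oi in seq_along(offsets))
        sim_counts[ev, oi] <- sum(ts >= offsets[oi] & ts < offsets[oi] + window)
    }
    rows <- lapply(seq_along(offsets), function(oi) {
      fb <- ff_boot(sim_counts[, oi], n_boot, "population")
      data.frame(group = 0L, offset = offsets[oi], mean_count = fb["mean"],
                 ff = fb["ff"], lo = fb["lo"], hi = fb["hi"],
                 binomial_min = if (fb["mean"] > 0) min_fano(fb["mean"])
                 else NA_real_)
    })
    curve <- do.call(rbind, rows)
    rownames(curve) <- NULL
    mf <- if (all(is.na(curve$ff))) NA_real_ else min(curve$ff, na.rm = TRUE)
    structure(list(curve = curve, min_ff = c(`0` = mf), min_ff_overall = mf,
                   window = window, offsets = offsets),
              class = "fano_curve")
  })
}

#' Fano factors under five alignment conditions
#'
#' Computes the spike-count Fano factor with increasingly fine alignment
#' to behavior: (1) counting over the whole pole-in-reach (sample)
#' period of each trial; (2) counting in random 38 ms windows inside the
#' sample period, matched per trial to the number of touches; (3)
#' counting in 38 ms windows starting 6 ms after each touch onset; (4)
#' the minimum sliding-window FF (10 ms window, offsets 0-20 ms) over
#' touches with long inter-contact intervals; (5) the same, with touches
#' divided into five stimulus-similarity groups (mean over the per-group
#' minima).
#'
#' @param session a session object (for traces/pole-in-reach).
#' @param kin per-trial kinematics from [session_kinematics()].
#' @param min_ici inter-contact-interval filter for conditions 4-5 (ms).
#' @param seed RNG seed (random windows, grouping bootstrap).
#' @param n_boot bootstrap resamples inside [sliding_fano()].
#' @return data frame: \code{condition} 1..5, \code{ff},
#'   \code{mean_count}, \code{description}.
#' @export
ff_conditions <- function(session, kin, min_ici = 250, seed = NULL,
                          n_boot = 200) {
  spikes <- session$spikes
  touches <- session$touches
  with_seed(seed, {
    # 1: whole sample period
    cnt1 <- vapply(session$traces, function(tr) {
      st <- spikes$time[spikes$trial_id == tr$trial_id]
      sum(st >= tr$pole_in_reach[1] & st < tr$pole_in_reach[2])
    }, numeric(1))
    # 2: random 38 ms windows, count matched to touches per trial
    cnt2 <- numeric(0)
    for (tr in session$traces) {
      ntch <- sum(touches$trial_id == tr$trial_id)
      if (ntch == 0L) next
      st <- spikes$time[spikes$trial_id == tr$trial_id]
      w0 <- stats::runif(ntch, tr$pole_in_reach[1], tr$pole_in_reach[2] - 38)
      cnt2 <- c(cnt2, vapply(w0, function(w)
        sum(st >= w & st < w + 38), numeric(1)))
    }
    # 3: 38 ms windows at touch onset + 6 ms
    cnt3 <- if (nrow(touches)) touch_spike_counts(spikes, touches, c(6, 44))
            else numeric(0)
    # 4 and 5: ICI-filtered touches, sliding windows
    sel <- select_touches(touches, min_ici)
    ff4 <- mean4 <- ff5 <- mean5 <- NA_real_
    if (nrow(sel) >= 2L) {
      sf4 <- sliding_fano(spikes, sel, window = 10, offsets = 0:20,
                          n_boot = n_boot, seed = derive_seed(seed %||% 0, 4))
      ff4 <- sf4$min_ff[["0"]]
      pooled <- sf4$curve[sf4$curve$group == 0L, ]
      mean4 <- pooled$mean_count[which.min(pooled$ff)]
      if (nrow(sel) >= 5 * 20) {
        grp <- group_touches(sel[, c("pretouch_velocity", "max_dkappa")])
        sf5 <- sliding_fano(spikes, sel, grouping = grp, window = 10,
                            offsets = 0:20, n_boot = n_boot,
                            seed = derive_seed(seed %||% 0, 5))
        per_group <- sf5$min_ff[setdiff(names(sf5$min_ff), "0")]
        ff5 <- mean(unlist(per_group), na.rm = TRUE)
        gcv <- sf5$curve[sf5$curve$group != 0L, ]
        at_min <- unlist(tapply(seq_len(nrow(gcv)), gcv$group, function(ii) {
          k <- which.min(gcv$ff[ii])
          if (length(k)) gcv$mean_count[ii][k] else NA_real_
        }))
        mean5 <- mean(at_min, na.rm = TRUE)
      }
    }
    safe_ff <- function(x) if (length(x) >= 2L && mean(x) > 0)
      fano_factor(x) else NA_real_
    data.frame(
      condition = 1:5,
      ff = c(safe_ff(cnt1), safe_ff(cnt2), safe_ff(cnt3), ff4, ff5),
      mean_count = c(mean(cnt1), if (length(cnt2)) mean(cnt2) else NA_real_,
                     if (length(cnt3)) mean(cnt3) else NA_real_, mean4, mean5),
      description = c("sample period", "random 38 ms windows",
                      "38 ms after touch + 6 ms latency",
                      "min sliding 10 ms FF",
                      "min sliding 10 ms FF, 5 similar-touch groups"))
  })
}
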