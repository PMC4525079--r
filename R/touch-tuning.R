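#' Touch-response tuning curve over a stimulus feature
#'
#' Sorts touches by a feature (touch order, pretouch velocity, or
#' maximum curvature change), splits them into \code{n_bins} bins with
#' equal numbers of touches (sizes differ by at most one; ties broken by
#' touch chronology via stable sort), and computes the mean spikes/touch
#' per bin with a bootstrap 95% confidence interval.
#'
#' @param counts per-touch spike counts (e.g. [touch_spike_counts()]).
#' @param feature_values numeric vector, same length as \code{counts};
#'   \code{NA} entries (e.g. undefined pretouch velocity) are dropped.
#' @param feature label for the curve.
#' @param n_bins number of equal-occupancy bins.
#' @param n_boot bootstrap resamples for the CI.
#' @param seed RNG seed for the bootstrap.
#' @return object of class \code{tuning_curve}: data frame \code{bins}
#'   (\code{bin}, \code{n}, \code{feature_lo}, \code{feature_hi},
#'   \code{mean}, \code{lo}, \code{hi}), \code{feature},
#'   \code{modulation_index}.
#' @export
bin_touch_responses <- function(counts, feature_values, feature = "feature",
                                n_bins = 10, n_boot = 1000, seed = NULL) {
  keep <- !is.na(feature_values)
  counts <- counts[keep]
  feature_values <- feature_values[keep]
  n <- length(counts)
  if (n < n_bins)
    stop(sprintf("need at least %d touches with a defined feature, got %d",
                 n_bins, n))
  o <- order(feature_values)  # stable: ties stay in chronological order
  sizes <- rep(n %/% n_bins, n_bins)
  extra <- n %% n_bins
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  idx_end <- cumsum(sizes)
  idx_start <- idx_end - sizes + 1L
  with_seed(seed, {
    rows <- lapply(seq_len(n_bins), function(b) {
      ii <- o[idx_start[b]:idx_end[b]]
      x <- counts[ii]
      bm <- replicate(n_boot, mean(x[sample.int(length(x), replace = TRUE)]))
      data.frame(bin = b, n = length(ii),
                 feature_lo = min(feature_values[ii]),
                 feature_hi = max(feature_values[ii]),
                 mean = mean(x),
                 lo = stats::quantile(bm, 0.025, names = FALSE),
                 hi = stats::quantile(bm, 0.975, names = FALSE))
    })
    bins <- do.call(rbind, rows)
    structure(list(bins = bins, feature = feature,
                   modulation_index = modulation_index(bins$mean)),
              class = "tuning_curve")
  })
}

#' Modulation index of a tuning curve
#'
#' \code{(max - min) / (max + min)} over the per-bin means; 0 for a flat
#' curve, 1 when the weakest bin is empty.  Undefined (\code{NA}, with a
#' warning) when every bin mean is zero.
#'
#' @param x a \code{tuning_curve} or a numeric vector of bin means.
#' @return numeric in \code{[0, 1]} or \code{NA}.
#' @export
modulation_index <- function(x) {
  m <- if (inherits(x, "tuning_curve")) x$bins$mean else as.numeric(x)
  if (all(m == 0)) {
    warning("all bin means are zero; modulation index undefined")
    return(NA_real_)
  }
  (max(m) - min(m)) / (max(m) + min(m))
}

#' @export
print.tuning_curve <- function(x, ...) {
  cat(sprintf("tuning_curve (%s): %d bins, modulation index %.3f\n",
              x$feature, nrow(x$bins), x$modulation_index))
  invisible(x)
}

#' Correlation of tuning across cells and features
#'
#' Pearson correlations between per-cell modulation indices (or any
#' per-cell tuning summaries) across feature types.
#'
#' @param index_matrix numeric matrix, cells x features (named columns).
#' @return correlation matrix; entries are \code{NA} (with a warning)
#'   when a feature column is constant.
#' @export
tuning_correlations <- function(index_matrix) {
  m <- as.matrix(index_matrix)
  if (nrow(m) < 3L) stop("need at least 3 cells")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    warning("constant tuning indices for: ",
            paste(colnames(m)[sds == 0], collapse = ", "),
            "; correlations undefined")
  suppressWarnings(stats::cor(m))
}
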