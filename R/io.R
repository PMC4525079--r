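# Session serialization (CSV tables + JSON manifest) and the pipeline
# driver.  Times are stored as ms floats at microsecond precision;
# intervals are 0-based and half-open throughout.

#' Write a session to a directory
#'
#' Writes \code{manifest.json} plus CSV tables: \code{whisker.csv}
#' (trial_id, time_ms, theta_deg, kappa), \code{events.csv} (trial_id,
#' type in touch_on/touch_off/lick/pole_in/pole_out, time_ms),
#' \code{spikes.csv} (trial_id, spike_time_ms), and, when present,
#' \code{ground_truth.csv}.
#'
#' @param session a session object ([generate_session()] or
#'   [read_session()]).
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- session$manifest
  manifest$trials <- vapply(session$traces, function(tr) tr$trial_id, numeric(1))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  wh <- do.call(rbind, lapply(session$traces, function(tr)
    data.frame(trial_id = tr$trial_id, time_ms = tr$t,
               theta_deg = round(tr$theta, 6), kappa = round(tr$kappa, 9))))
  utils::write.csv(wh, file.path(dir, "whisker.csv"), row.names = FALSE)
  ev <- do.call(rbind, lapply(session$traces, function(tr) {
    out <- data.frame(trial_id = numeric(0), type = character(0),
                      time_ms = numeric(0))
    add <- function(type, t) if (length(t))
      rbind(out, data.frame(trial_id = tr$trial_id, type = type, time_ms = t))
    else out
    out <- add("pole_in", tr$pole_in_reach[1])
    out <- add("pole_out", tr$pole_in_reach[2])
    if (nrow(tr$touch_intervals)) {
      out <- add("touch_on", tr$touch_intervals[, 1])
      out <- add("touch_off", tr$touch_intervals[, 2])
    }
    out <- add("lick", tr$lick_times)
    out[order(out$time_ms), ]
  }))
  utils::write.csv(ev, file.path(dir, "events.csv"), row.names = FALSE)
  utils::write.csv(data.frame(trial_id = session$spikes$trial_id,
                              spike_time_ms = round(session$spikes$time, 3)),
                   file.path(dir, "spikes.csv"), row.names = FALSE)
  if (!is.null(session$ground_truth) && nrow(session$ground_truth))
    utils::write.csv(session$ground_truth, file.path(dir, "ground_truth.csv"),
                     row.names = FALSE)
  invisible(dir)
}

read_table_checked <- function(dir, file, cols) {
  path <- file.path(dir, file)
  if (!file.exists(path)) stop("missing session file: ", path)
  tab <- utils::read.csv(path)
  missing <- setdiff(cols, names(tab))
  if (length(missing))
    stop("schema error in ", file, ": missing column(s) ",
         paste(missing, collapse = ", "))
  tab
}

#' Read a session from a directory
#'
#' Reads and validates the tables written by [write_session()]:
#' referential integrity of trial ids against the manifest, spike times
#' within trial bounds (violations reported with row numbers), sorted
#' spike times (auto-sorted with a warning).
#'
#' @param dir directory containing \code{manifest.json} and the CSVs.
#' @return a session object (class \code{wt_session}).
#' @export
read_session <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop("missing session file: ", mpath)
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  wh <- read_table_checked(dir, "whisker.csv",
                           c("trial_id", "time_ms", "theta_deg", "kappa"))
  ev <- read_table_checked(dir, "events.csv",
                           c("trial_id", "type", "time_ms"))
  sp <- read_table_checked(dir, "spikes.csv", c("trial_id", "spike_time_ms"))
  ids <- sort(unique(wh$trial_id))
  if (!is.null(manifest$trials) && !setequal(ids, manifest$trials))
    stop("trial ids in whisker.csv do not match the manifest")
  traces <- vector("list", length(ids))
  touch_list <- vector("list", length(ids))
  for (j in seq_along(ids)) {
    id <- ids[j]
    wi <- wh[wh$trial_id == id, ]
    wi <- wi[order(wi$time_ms), ]
    evi <- ev[ev$trial_id == id, ]
    t_on <- sort(evi$time_ms[evi$type == "touch_on"])
    t_off <- sort(evi$time_ms[evi$type == "touch_off"])
    if (length(t_on) != length(t_off))
      stop("trial ", id, ": touch_on/touch_off events do not pair up")
    pole_in <- evi$time_ms[evi$type == "pole_in"]
    pole_out <- evi$time_ms[evi$type == "pole_out"]
    traces[[j]] <- whisker_trace(
      trial_id = id, theta = wi$theta_deg, kappa = wi$kappa,
      lick_times = evi$time_ms[evi$type == "lick"],
      pole_in_reach = c(if (length(pole_in)) pole_in[1] else 0,
                        if (length(pole_out)) pole_out[1] else nrow(wi)),
      touch_intervals = if (length(t_on)) cbind(t_on, t_off) else iv_empty())
    touch_list[[j]] <- extract_touch_features(traces[[j]])
  }
  names(traces) <- NULL
  bad <- which(!sp$trial_id %in% ids)
  if (length(bad))
    stop("spikes.csv: unknown trial_id at row(s) ",
         paste(utils::head(bad, 10), collapse = ", "))
  dur <- vapply(traces, function(tr) length(tr$theta), numeric(1))
  names(dur) <- vapply(traces, function(tr) as.character(tr$trial_id),
                       character(1))
  out_of_bounds <- which(sp$spike_time_ms < 0 |
                           sp$spike_time_ms >= dur[as.character(sp$trial_id)])
  if (length(out_of_bounds))
    stop("spikes.csv: spike time outside trial bounds at row(s) ",
         paste(utils::head(out_of_bounds, 10), collapse = ", "))
  spikes <- data.frame(trial_id = sp$trial_id, time = sp$spike_time_ms)
  resort <- unsplit(lapply(split(seq_len(nrow(spikes)), spikes$trial_id),
                           function(ii) ii[order(spikes$time[ii])]),
                    spikes$trial_id)
  if (!identical(resort, seq_len(nrow(spikes)))) {
    warning("spike times were not sorted within trials; sorting")
    spikes <- spikes[order(spikes$trial_id, spikes$time), ]
    rownames(spikes) <- NULL
  }
  gt <- NULL
  if (file.exists(file.path(dir, "ground_truth.csv")))
    gt <- utils::read.csv(file.path(dir, "ground_truth.csv"))
  structure(list(manifest = manifest, config = NULL, traces = traces,
                 touches = do.call(rbind, touch_list), spikes = spikes,
                 ground_truth = gt, truth = NULL),
            class = "wt_session")
}

#' Pipeline configuration
#'
#' @param seed master seed; every stochastic stage derives its own
#'   stream from it.
#' @param n_shuffle shuffles for the attribution chance curves.
#' @param n_boot bootstrap resamples for Fano CIs.
#' @param min_ici inter-contact-interval filter (ms) for the grouped
#'   Fano analysis.
#' @param decode run the decoding stage (single-session populations are
#'   resampled copies of the one recorded neuron).
#' @param decode_n population sizes for the decoding stage.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(seed = 1L, n_shuffle = 1000, n_boot = 1000,
                            min_ici = 250, decode = TRUE,
                            decode_n = c(1, 5, 15)) {
  structure(list(seed = as.integer(seed), n_shuffle = n_shuffle,
                 n_boot = n_boot, min_ici = min_ici, decode = decode,
                 decode_n = decode_n),
            class = "pipeline_config")
}

#' Run the full analysis pipeline on one session
#'
#' Executes kinematics, spike metrics, attribution, touch tuning, the
#' Fano analysis and (optionally) decoding, in order, and returns all
#' stage outputs plus a flat summary.  With \code{out_dir}, stage tables
#' are written as CSV and the summary as JSON.
#'
#' @param session a session object.
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return list of class \code{pipeline_result}: \code{kin},
#'   \code{psth}, \code{latency}, \code{tuning}, \code{rates},
#'   \code{attribution}, \code{touch_tuning} (list per feature),
#'   \code{fano} (list: \code{selected}, \code{grouping},
#'   \code{sliding}, \code{conditions}), \code{decoding} (or NULL),
#'   \code{summary} (named list of scalars).
#' @export
run_pipeline <- function(session, config = pipeline_config(),
                         out_dir = NULL) {
  kin <- session_kinematics(session)
  spikes <- session$spikes
  touches <- session$touches

  psth <- touch_aligned_psth(spikes, touches, "all_touch")
  latency <- onset_latency(psth)
  tuning <- phase_tuning(spikes, kin)
  att <- touch_coupled_fraction(spikes, kin,
                                latency = if (is.na(latency)) 0 else latency,
                                n_shuffle = config$n_shuffle,
                                seed = derive_seed(config$seed, 11))
  res <- phase_coupled_fraction(att, spikes, kin,
                                phase_pref = tuning$phase_pref %||% 0,
                                n_shuffle = config$n_shuffle,
                                seed = derive_seed(config$seed, 12))
  resp_window <- c(att$latency,
                   att$latency + if (is.na(att$t_on)) 30 else att$t_on)
  rates <- epoch_rates(spikes, kin, touches, window = resp_window)

  counts <- touch_spike_counts(spikes, touches, resp_window)
  tt <- list()
  for (feat in c("order", "pretouch_velocity", "max_dkappa")) {
    tt[[feat]] <- tryCatch(
      bin_touch_responses(counts, touches[[feat]], feature = feat,
                          n_boot = config$n_boot,
                          seed = derive_seed(config$seed, 21)),
      error = function(e) NULL)
  }

  sel <- select_touches(touches, config$min_ici)
  grouping <- NULL
  sliding <- NULL
  if (nrow(sel) >= 100) {
    grouping <- group_touches(sel[, c("pretouch_velocity", "max_dkappa")])
    sliding <- sliding_fano(spikes, sel, grouping,
                            n_boot = config$n_boot,
                            seed = derive_seed(config$seed, 31))
  } else if (nrow(sel) >= 2) {
    sliding <- sliding_fano(spikes, sel, n_boot = config$n_boot,
                            seed = derive_seed(config$seed, 31))
  }
  conditions <- ff_conditions(session, kin, min_ici = config$min_ici,
                              seed = derive_seed(config$seed, 32))

  decoding <- NULL
  if (isTRUE(config$decode)) {
    neuron <- decoder_neuron_from_session(session, kin,
                                          seed = derive_seed(config$seed, 41))
    pres <- decode_touch_presence(list(neuron), n_grid = config$decode_n,
                                  n_rep = 10,
                                  seed = derive_seed(config$seed, 42))
    decoding <- list(presence = pres)
  }

  summary <- list(
    n_trials = session$manifest$n_trials,
    n_touches = nrow(touches),
    n_spikes = nrow(spikes),
    latency_ms = latency,
    modulation_depth = tuning$modulation_depth,
    phase_pref_rad = tuning$phase_pref,
    whisking_rate = rates$whisking_rate,
    non_whisking_rate = rates$non_whisking_rate,
    min_isi_ms = rates$min_isi,
    spikes_per_touch = mean(counts),
    frac_touch = res$frac_touch,
    frac_touch_or_phase = res$frac_touch_or_phase,
    occupancy_touch = res$occupancy_touch,
    t_on_ms = res$t_on,
    min_ff = if (!is.null(sliding)) sliding$min_ff_overall else NA_real_,
    ff_condition_1 = conditions$ff[1], ff_condition_2 = conditions$ff[2],
    ff_condition_3 = conditions$ff[3], ff_condition_4 = conditions$ff[4],
    ff_condition_5 = conditions$ff[5],
    seed = config$seed)

  out <- structure(list(kin = kin, psth = psth, latency = latency,
                        tuning = tuning, rates = rates, attribution = res,
                        attribution_curves = att, touch_tuning = tt,
                        fano = list(selected = sel, grouping = grouping,
                                    sliding = sliding,
                                    conditions = conditions),
                        decoding = decoding, summary = summary),
                   class = "pipeline_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(data.frame(t = att$t, y = att$y,
                                chance_slope = att$chance_slope),
                     file.path(out_dir, "attribution_curve.csv"),
                     row.names = FALSE)
    if (!is.null(sliding))
      utils::write.csv(sliding$curve, file.path(out_dir, "fano_curve.csv"),
                       row.names = FALSE)
    utils::write.csv(conditions, file.path(out_dir, "ff_conditions.csv"),
                     row.names = FALSE)
    tunes <- do.call(rbind, lapply(Filter(Negate(is.null), tt), function(x)
      cbind(feature = x$feature, x$bins)))
    if (!is.null(tunes))
      utils::write.csv(tunes, file.path(out_dir, "touch_tuning.csv"),
                       row.names = FALSE)
    # epochs as a BED-like interval table
    eps <- do.call(rbind, lapply(names(kin), function(tid) {
      ep <- kin[[tid]]$epochs
      mk <- function(ivx, lab) if (nrow(ivx))
        data.frame(trial_id = as.integer(tid), start_ms = ivx[, 1],
                   end_ms = ivx[, 2], label = lab) else NULL
      rbind(mk(ep$whisking, "whisking"), mk(ep$non_whisking, "non_whisking"),
            mk(ep$touch, "touch"), mk(ep$exploration, "exploration"))
    }))
    if (!is.null(eps))
      utils::write.csv(eps, file.path(out_dir, "epochs.csv"),
                       row.names = FALSE)
  }
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$summary
  cat("pipeline_result\n")
  cat(sprintf("  trials %s, touches %s, spikes %s\n", s$n_trials, s$n_touches,
              s$n_spikes))
  cat(sprintf("  latency %s ms, depth %.2f, frac_touch %.2f, min FF %.2f\n",
              format(s$latency_ms), s$modulation_depth, s$frac_touch,
              s$min_ff))
  invisible(x)
}
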