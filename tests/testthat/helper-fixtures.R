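# Shared fixtures: cached synthetic sessions and hand-built kinematic
# objects for boundary-exact tests.

.session_cache <- new.env(parent = emptyenv())

# Memoised session + kinematics so expensive fixtures build once per run.
cached_session <- function(key, cfg) {
  if (!exists(key, envir = .session_cache)) {
    s <- generate_session(cfg)
    assign(key, list(session = s, kin = session_kinematics(s)),
           envir = .session_cache)
  }
  get(key, envir = .session_cache)
}

default_session <- function() {
  cached_session("default100", generator_config(n_trials = 100, seed = 42))
}

# Sawtooth phase series: cycles of fixed length, amplitude amp everywhere.
# Phase rises linearly from -pi to pi within each cycle, so spike time t
# maps to phase 2*pi*(t mod L)/L - pi.
fake_phase <- function(n_ms, cycle_len = 100, amp = 5) {
  t <- seq_len(n_ms) - 1
  phi <- 2 * pi * ((t %% cycle_len) / cycle_len) - pi
  starts <- seq(0, n_ms - cycle_len, by = cycle_len)
  cycles <- data.frame(start = starts, end = starts + cycle_len,
                       p2p = 2 * amp, monotonic = TRUE)
  structure(list(trial_id = 1L, t = t, theta_band = amp * cos(phi),
                 phi = phi, amplitude = rep(amp, n_ms), cycles = cycles,
                 fs = 1000),
            class = "phase_series")
}

# Epoch set wrapping a fake phase series: everything is whisking and
# exploration; phase_ok for all cycles.
fake_epochs <- function(phase, touches = NULL,
                        non_whisking = matrix(numeric(0), ncol = 2)) {
  cyc <- phase$cycles
  cyc$whisking <- TRUE
  cyc$phase_ok <- TRUE
  n_ms <- length(phase$t)
  structure(list(whisking = cbind(0, n_ms), non_whisking = non_whisking,
                 touch = if (is.null(touches)) matrix(numeric(0), ncol = 2)
                         else cbind(touches$onset, touches$offset),
                 exploration = cbind(0, n_ms), cycles = cyc),
            class = "epoch_set")
}

# Minimal kin container for one trial.
fake_kin <- function(phase, epochs, touches = NULL) {
  if (is.null(touches))
    touches <- data.frame(trial_id = integer(0), onset = numeric(0),
                          offset = numeric(0), order = integer(0),
                          ici = numeric(0), pretouch_velocity = numeric(0),
                          max_dkappa = numeric(0), is_first = logical(0))
  stats::setNames(list(list(phase = phase, epochs = epochs,
                            touches = touches)), "1")
}

touch_table <- function(onsets, durations = 30, trial_id = 1L) {
  n <- length(onsets)
  offs <- onsets + rep(durations, length.out = n)
  data.frame(trial_id = trial_id, onset = onsets, offset = offs,
             order = seq_len(n),
             ici = c(Inf, onsets[-1] - offs[-n]),
             pretouch_velocity = 0.4, max_dkappa = 0.003,
             is_first = seq_len(n) == 1L)
}
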