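# EMG and kinematic conditioning.
#
# The EMG chain is: 4th-order Butterworth band-pass (10-450 Hz), full-wave
# rectification, 4th-order Butterworth low-pass (40 Hz). Both stages are
# applied zero-phase (forward-backward) so the envelope is not lagged, which
# matters because reactive activity is summarised in 100-150 ms bins.
# Envelopes are scaled per subject and muscle by the maximum filtered value
# across all of that subject's trials, so 1 is each subject's own maximum.

#' Analysis time grid
#'
#' Uniform grid at the analysis rate (default 100 Hz) over the analysis
#' window (default -0.6 to 1.5 s), time zero at perturbation onset.
#'
#' @param rate Samples per second.
#' @param window Two-element window in seconds relative to onset.
#' @return Numeric vector of times.
#' @export
analysis_grid <- function(rate = 100, window = c(-0.6, 1.5)) {
  seq(window[1], window[2], by = 1 / rate)
}

#' EMG envelope extraction
#'
#' Band-pass, rectify, low-pass (all zero-phase). Residual negative
#' undershoot from low-pass ringing is floored at zero: a rectified signal
#' is non-negative by meaning.
#'
#' @param raw Raw EMG samples.
#' @param fs Sampling rate (Hz); must exceed 900 Hz so the 450 Hz band edge
#'   stays below Nyquist.
#' @param band Band-pass edges in Hz (default `c(10, 450)`).
#' @param lowpass Envelope low-pass cutoff in Hz (default 40).
#' @param order Butterworth design order per pass (default 4).
#' @return Envelope, same length as `raw`, non-negative.
#' @export
filter_emg <- function(raw, fs, band = c(10, 450), lowpass = 40, order = 4) {
  if (fs <= 2 * band[2]) {
    stop("sampling rate ", fs, " Hz too low for a ", band[2],
         " Hz band edge (need fs > ", 2 * band[2], ")")
  }
  bp <- butter_sos(order, band, fs, "band")
  lp <- butter_sos(order, lowpass, fs, "low")
  env <- sos_filtfilt(lp, abs(sos_filtfilt(bp, raw)))
  pmax(env, 0)
}

#' Subject-maximum EMG scaling
#'
#' Divides every envelope of one subject and muscle by the single maximum
#' filtered value across all provided trials, so that the subject's maximum
#' over the whole protocol is 1. Idempotent: rescaling scaled data returns
#' scale factor 1.
#'
#' @param envelopes List of numeric envelopes (all trials of one subject,
#'   one muscle).
#' @return List with `envelopes` (scaled) and `scale` (the divisor).
#' @export
scale_emg <- function(envelopes) {
  if (!length(envelopes)) stop("no trials supplied")
  mx <- max(vapply(envelopes, function(e) max(e, na.rm = TRUE), numeric(1)))
  if (!is.finite(mx) || mx <= 0) {
    stop("degenerate channel: maximum envelope is not positive")
  }
  list(envelopes = lapply(envelopes, function(e) e / mx), scale = mx)
}

#' Numerical differentiation on a uniform grid
#'
#' Central differences in the interior, one-sided differences at the ends.
#'
#' @param x Signal.
#' @param fs Sampling rate (Hz).
#' @return Derivative, units of `x` per second.
#' @export
differentiate <- function(x, fs) {
  n <- length(x)
  if (n < 3) stop("need at least 3 samples to differentiate")
  v <- numeric(n)
  v[1] <- (x[2] - x[1]) * fs
  v[n] <- (x[n] - x[n - 1]) * fs
  idx <- 2:(n - 1)
  v[idx] <- (x[idx + 1] - x[idx - 1]) * fs / 2
  v
}

#' Acceleration from velocity by Savitzky-Golay differentiation
#'
#' First-derivative Savitzky-Golay filter, polynomial order 5, window 11
#' samples (interior exact for quintics; edges use one-sided fits).
#'
#' @param vel Velocity series on a uniform grid.
#' @param fs Sampling rate (Hz).
#' @param order,window Savitzky-Golay design (defaults 5, 11).
#' @return Acceleration series.
#' @export
sg_acceleration <- function(vel, fs, order = 5, window = 11) {
  savgol_deriv(vel, fs, order = order, window = window)
}

#' Resample a trial onto the common analysis grid
#'
#' Linearly interpolates the kinematic channels and the supplied EMG
#' envelopes onto the analysis grid, re-referenced so perturbation onset is
#' time zero.
#'
#' @param rec A [trial_recording()].
#' @param envelopes Named list of per-muscle envelopes on the trial's
#'   `time_s` axis (typically from [filter_emg()], or the stored channels
#'   when `emg_kind == "envelope"`).
#' @param rate Analysis rate (Hz, default 100).
#' @param window Analysis window in seconds relative to onset.
#' @return A `processed_trial`: list with `grid`, per-muscle `emg_env`,
#'   `com_pos`, `ankle_angle` and the trial metadata.
#' @export
resample_common_grid <- function(rec, envelopes = NULL, rate = 100,
                                 window = c(-0.6, 1.5)) {
  grid <- analysis_grid(rate, window)
  t_rel <- rec$time_s - rec$onset_time
  tol <- 1e-9
  if (min(t_rel) > window[1] + tol || max(t_rel) < window[2] - tol) {
    stop(sprintf(
      "trial covers [%.3f, %.3f] s but the analysis window is [%.2f, %.2f] s",
      min(t_rel), max(t_rel), window[1], window[2]
    ))
  }
  if (is.null(envelopes)) envelopes <- rec$emg
  interp <- function(y) approx(t_rel, y, xout = grid, rule = 1)$y
  structure(
    list(
      subject_id = rec$subject_id, group = rec$group, level = rec$level,
      trial_index = rec$trial_index, stepped = rec$stepped,
      grid = grid, rate = rate,
      emg_env = lapply(envelopes[MUSCLES], interp),
      com_pos = interp(rec$com_pos),
      ankle_angle = interp(rec$ankle_angle)
    ),
    class = "processed_trial"
  )
}

#' Average processed trials
#'
#' Pointwise mean of every channel across non-stepping trials on identical
#' grids. Stepped trials passed in are rejected.
#'
#' @param trials List of `processed_trial` objects.
#' @return A single `processed_trial` with `trial_index = NA` and `n_trials`
#'   recording how many trials entered the average.
#' @export
average_trials <- function(trials) {
  if (!length(trials)) {
    stop("no non-stepping trials to average (subject-level missing data)")
  }
  stepped <- vapply(trials, function(tr) isTRUE(tr$stepped), logical(1))
  if (any(stepped)) {
    stop(sum(stepped), " stepped trial(s) passed to average_trials; ",
         "exclude them first")
  }
  g0 <- trials[[1]]$grid
  for (tr in trials) {
    if (length(tr$grid) != length(g0) || any(abs(tr$grid - g0) > 1e-9)) {
      stop("trials are not on identical grids")
    }
  }
  mean_of <- function(get) {
    Reduce(`+`, lapply(trials, get)) / length(trials)
  }
  out <- trials[[1]]
  out$trial_index <- NA_integer_
  out$n_trials <- length(trials)
  out$com_pos <- mean_of(function(tr) tr$com_pos)
  out$ankle_angle <- mean_of(function(tr) tr$ankle_angle)
  out$emg_env <- setNames(
    lapply(MUSCLES, function(m) mean_of(function(tr) tr$emg_env[[m]])),
    MUSCLES
  )
  out
}

#' Delayed-feedback kinematic inputs from a processed trial
#'
#' Computes CoM velocity (central differences of position), CoM
#' acceleration (Savitzky-Golay derivative of velocity), and the
#' stiction-gated initial acceleration `a_init` (equal to the acceleration
#' from onset until the ankle angle has changed by `stiction_threshold`
#' degrees, zero elsewhere).
#'
#' @param processed A `processed_trial` (typically trial-averaged).
#' @param stiction_threshold Ankle-angle change (deg) that closes the
#'   stiction gate (default 0.5).
#' @return A `com_kinematics` object: `grid`, `d`, `v`, `a`, `a_init`,
#'   `ankle`, `ankle_v`, `ankle_a`, `rate`.
#' @export
com_kinematics <- function(processed, stiction_threshold = 0.5) {
  fs <- processed$rate
  d <- processed$com_pos
  v <- differentiate(d, fs)
  a <- sg_acceleration(v, fs)
  ankle <- processed$ankle_angle
  ankle_v <- differentiate(ankle, fs)
  ankle_a <- sg_acceleration(ankle_v, fs)
  a_init <- gate_stiction(a, ankle, processed$grid, stiction_threshold)
  structure(
    list(grid = processed$grid, rate = fs, d = d, v = v, a = a,
         a_init = a_init, ankle = ankle, ankle_v = ankle_v,
         ankle_a = ankle_a),
    class = "com_kinematics"
  )
}

#' Full preprocessing of one trial
#'
#' Applies the EMG chain when the stored channels are raw, resamples onto
#' the analysis grid. Scaling across trials is a separate, subject-level
#' step ([scale_emg()]), because the scale factor pools all trials.
#'
#' @param rec A [trial_recording()].
#' @param config Preprocessing block of the pipeline configuration (see
#'   [default_config()]).
#' @return A `processed_trial` (unscaled).
#' @export
preprocess_trial <- function(rec, config = default_config()$preprocess) {
  envs <- if (rec$emg_kind == "raw") {
    lapply(rec$emg, filter_emg, fs = rec$emg_rate,
           band = config$band, lowpass = config$lowpass)
  } else {
    rec$emg
  }
  resample_common_grid(rec, envs, rate = config$analysis_rate,
                       window = config$window)
}
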