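# Shared fixture builders. Everything is generated in code; no data files.

# A minimal trial_recording with analytic channels on the standard grid.
make_test_trial <- function(subject_id = "S01", group = "TD", level = 2,
                            trial_index = 1, stepped = FALSE,
                            onset_time = 1.0, rate = 100,
                            emg_value = 0.2) {
  grid <- analysis_grid(rate)
  const <- function(v) rep(v, length(grid))
  trial_recording(
    subject_id = subject_id, group = group, level = level,
    trial_index = trial_index, stepped = stepped, onset_time = onset_time,
    time_s = grid + onset_time,
    com_pos = 0.02 * pmax(sin(pi * pmax(grid, 0) / 0.8), 0),
    ankle_angle = 3 * pmin(pmax(grid, 0) / 0.5, 1),
    emg = list(LG = const(emg_value), MG = const(emg_value),
               SOL = const(emg_value), TA = const(emg_value)),
    emg_rate = rate, kin_rate = rate, emg_kind = "envelope"
  )
}

# com_kinematics built directly from supplied series (bypasses derivative
# computation) for unit tests that need exact regressors.
make_test_com <- function(grid, d = NULL, v = NULL, a = NULL,
                          a_init = NULL, ankle = NULL) {
  z <- numeric(length(grid))
  structure(
    list(grid = grid, rate = round(1 / (grid[2] - grid[1])),
         d = d %||% z, v = v %||% z, a = a %||% z,
         a_init = a_init %||% z, ankle = ankle %||% z,
         ankle_v = z, ankle_a = z),
    class = "com_kinematics"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Kinematics of a default synthetic trial (noiseless), cached per level.
synth_com <- local({
  cache <- list()
  function(level = 2, config = model_config()) {
    key <- as.character(level)
    if (is.null(cache[[key]])) {
      tr <- comfeedback:::generate_trial(
        "SX", "TD", level, 1, archetype_gains("TD_like"),
        noise_model(0, 0.05, 0), config = config
      )
      pp <- preprocess_trial(tr)
      cache[[key]] <<- list(trial = tr, processed = pp,
                            com = com_kinematics(pp))
    }
    cache[[key]]
  }
})
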