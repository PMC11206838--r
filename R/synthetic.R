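# Synthetic perturbation data with known ground truth.
#
# The generator is signal-level, not mechanistic: it produces CoM and ankle
# trajectories with the qualitative structure of a combined backward
# platform translation + delayed toe-up rotation (forward CoM excursion
# that reverses once, early monotone dorsiflexion crossing 0.5 degrees
# within ~150 ms), then produces EMG envelopes by running the feedback
# model forward from known gains and adding clipped Gaussian envelope
# noise. Because EMG is generated by the same equations the fitter
# inverts, parameter recovery is a meaningful end-to-end check.
#
# Smooth pulses are raised-cosine steps, which are C1, start and end at
# rest, and have closed-form derivatives.

# raised-cosine step from 0 to 1 over [t0, t0 + dur]
rc_step <- function(t, t0, dur) {
  u <- pmin(pmax((t - t0) / dur, 0), 1)
  0.5 * (1 - cos(pi * u))
}
rc_step_vel <- function(t, t0, dur) {
  u <- (t - t0) / dur
  ifelse(u > 0 & u < 1, pi / (2 * dur) * sin(pi * u), 0)
}
rc_step_acc <- function(t, t0, dur) {
  u <- (t - t0) / dur
  ifelse(u > 0 & u < 1, pi^2 / (2 * dur^2) * cos(pi * u), 0)
}

# Default platform amplitude table. Translation displacement repeats
# (L1 = L2, L3 = L4) while shrinking durations make peak velocity and
# acceleration grow with every level; rotation amplitude grows each level.
PROFILE_DEFAULTS <- list(
  trans_disp_m = c(0.05, 0.05, 0.10, 0.10),
  trans_dur_s = c(0.50, 0.38, 0.50, 0.42),
  rot_amp_deg = c(4, 6, 8, 10),
  rot_delay_s = 0.15,
  rot_dur_s = 0.40
)

#' Platform perturbation profile
#'
#' Backward translation plus delayed toe-up rotation, both raised-cosine
#' displacement pulses. The profile starts and ends at rest; per-level peak
#' platform velocity and acceleration increase monotonically with level.
#'
#' @param level Perturbation level 1-4.
#' @param params Amplitude table (see `PROFILE_DEFAULTS`): translation
#'   displacement (m) and duration (s), rotation amplitude (deg), delay and
#'   duration (s), per level (recycled if scalar).
#' @param rate Sampling rate of the returned series (Hz).
#' @param duration Total profile duration (s).
#' @return A `perturbation_profile`: sampled displacement/velocity/
#'   acceleration of translation (m, backward negative) and rotation (deg,
#'   toe-up positive), plus the closed-form parameters.
#' @export
make_profile <- function(level, params = PROFILE_DEFAULTS, rate = 100,
                         duration = 1.5) {
  if (!level %in% 1:4) stop("level must be in 1..4")
  pick <- function(x) if (length(x) >= level) x[[level]] else x[[1]]
  D <- pick(params$trans_disp_m)
  Td <- pick(params$trans_dur_s)
  R <- pick(params$rot_amp_deg)
  t0r <- pick(params$rot_delay_s)
  Tr <- pick(params$rot_dur_s)
  if (D < 0 || R < 0) stop("profile amplitudes must be non-negative")
  if (Td <= 0 || Tr <= 0) stop("profile durations must be positive")
  t <- seq(0, duration, by = 1 / rate)
  structure(
    list(
      level = level, time = t, duration = duration,
      trans_disp = -D * rc_step(t, 0, Td),
      trans_vel = -D * rc_step_vel(t, 0, Td),
      trans_acc = -D * rc_step_acc(t, 0, Td),
      rot_angle = R * rc_step(t, t0r, Tr),
      rot_vel = R * rc_step_vel(t, t0r, Tr),
      rot_acc = R * rc_step_acc(t, t0r, Tr),
      trans_amp = D, trans_dur = Td, rot_amp = R,
      rot_delay = t0r, rot_dur = Tr,
      peak_trans_vel = D * pi / (2 * Td),
      peak_rot_vel = R * pi / (2 * Tr)
    ),
    class = "perturbation_profile"
  )
}

# Default body-response parameters: how platform motion maps to CoM and
# ankle trajectories. Forward CoM excursion scales with peak translation
# velocity; the backward excursion and the dorsiflexion amplitude scale
# with rotation amplitude. Timing gives a forward peak near 0.35 s, a
# single velocity reversal, and a 0.5 degree ankle change before 150 ms.
RESPONSE_DEFAULTS <- list(
  com_fwd_per_vel = 0.15,   # s: forward CoM amplitude per m/s platform vel
  com_bwd_per_deg = 0.004,  # m/deg: backward CoM amplitude per deg rotation
  fwd_t0 = 0.03, fwd_dur = 0.35,
  bwd_t0 = 0.30, bwd_dur = 0.55,
  ankle_per_deg = 0.7,      # deg/deg: ankle dorsiflexion per deg rotation
  ankle_t0 = 0.00, ankle_dur = 0.50
)

#' CoM and ankle trajectories induced by a perturbation profile
#'
#' @param profile A [make_profile()] result.
#' @param response_params Body-response table (see `RESPONSE_DEFAULTS`).
#' @param grid Analysis time axis (s, onset at 0); default the standard
#'   grid.
#' @return List with `grid`, `com_pos` (m, anterior positive, one velocity
#'   reversal), and `ankle_angle` (deg, dorsiflexion positive).
#' @export
make_com_ankle <- function(profile, response_params = RESPONSE_DEFAULTS,
                           grid = analysis_grid()) {
  rp <- utils::modifyList(RESPONSE_DEFAULTS, response_params)
  a_fwd <- rp$com_fwd_per_vel * profile$peak_trans_vel
  a_bwd <- rp$com_bwd_per_deg * profile$rot_amp
  com <- a_fwd * rc_step(grid, rp$fwd_t0, rp$fwd_dur) -
    (a_fwd + a_bwd) * rc_step(grid, rp$bwd_t0, rp$bwd_dur)
  ankle <- rp$ankle_per_deg * profile$rot_amp *
    rc_step(grid, rp$ankle_t0, rp$ankle_dur)
  list(grid = grid, com_pos = com, ankle_angle = ankle)
}

#' Noise model for synthetic EMG envelopes
#'
#' @param envelope_sd Additive Gaussian noise on the envelope (normalised
#'   EMG units, default 0.02); the noisy envelope is clipped at 0.
#' @param baseline Tonic baseline activity `e0` (default 0.05).
#' @param kin_jitter_sd Relative trial-to-trial amplitude jitter of the
#'   kinematics (default 0.02).
#' @return A `noise_model` list.
#' @export
noise_model <- function(envelope_sd = 0.02, baseline = 0.05,
                        kin_jitter_sd = 0.02) {
  if (envelope_sd < 0) stop("envelope noise sd must be >= 0")
  if (baseline < 0) stop("baseline must be >= 0")
  if (kin_jitter_sd < 0) stop("kinematic jitter sd must be >= 0")
  list(envelope_sd = envelope_sd, baseline = baseline,
       kin_jitter_sd = kin_jitter_sd)
}

# Ground-truth gain archetypes. TD_like prime gains are near zero; CP_like
# has elevated balance-correcting gains and a 5x prime velocity gain,
# which yields sustained plantar flexor activity after the CoM reversal
# and clearly separated co-contraction indices.
GAIN_ARCHETYPES <- list(
  TD_like = list(
    LG  = c(k_d = 1.0, k_v = 0.8, k_a = 0.15, k_s = 0.20,
            k_dp = 0.05, k_vp = 0.08, k_ap = 0.05),
    MG  = c(k_d = 0.9, k_v = 0.7, k_a = 0.12, k_s = 0.18,
            k_dp = 0.05, k_vp = 0.08, k_ap = 0.04),
    SOL = c(k_d = 1.1, k_v = 0.9, k_a = 0.18, k_s = 0.22,
            k_dp = 0.06, k_vp = 0.08, k_ap = 0.05),
    TA  = c(k_d = 0.8, k_v = 0.6, k_a = 0.10,
            k_dp = 0.05, k_vp = 0.08, k_ap = 0.05)
  ),
  CP_like = list(
    LG  = c(k_d = 1.8, k_v = 1.6, k_a = 0.25, k_s = 0.30,
            k_dp = 0.15, k_vp = 0.40, k_ap = 0.15),
    MG  = c(k_d = 1.6, k_v = 1.4, k_a = 0.20, k_s = 0.27,
            k_dp = 0.15, k_vp = 0.40, k_ap = 0.12),
    SOL = c(k_d = 2.0, k_v = 1.8, k_a = 0.28, k_s = 0.33,
            k_dp = 0.18, k_vp = 0.40, k_ap = 0.15),
    TA  = c(k_d = 1.2, k_v = 1.5, k_a = 0.15,
            k_dp = 0.20, k_vp = 0.40, k_ap = 0.10)
  )
)

#' Ground-truth gains for a group archetype
#'
#' @param archetype `"TD_like"` or `"CP_like"`.
#' @return Named list of per-muscle gain vectors, all within the model
#'   bounds.
#' @export
archetype_gains <- function(archetype = c("TD_like", "CP_like")) {
  GAIN_ARCHETYPES[[match.arg(archetype)]]
}

# Draw one subject's gains around an archetype: independent lognormal
# multipliers, truncated to the gain box.
draw_subject_gains <- function(archetype_gain_list, sigma = 0.25,
                               upper = 10) {
  lapply(archetype_gain_list, function(g) {
    pmin(g * exp(rnorm(length(g), 0, sigma)), upper)
  })
}

#' Generate EMG envelopes from known feedback gains
#'
#' Forward application of the feedback model plus clipped additive
#' Gaussian envelope noise: `envelope = |model| + N(0, sd)`, floored at 0.
#'
#' @param com A [com_kinematics()] object on the analysis grid.
#' @param gains_list Named list of per-muscle gain vectors (`LG`, `MG`,
#'   `SOL`, `TA`).
#' @param e0 Baseline activity added to the balance-correcting pathway.
#' @param noise_sd Envelope noise standard deviation (>= 0). Noise is drawn
#'   from the current RNG state: seed upstream for reproducibility.
#' @param config A [model_config()].
#' @return Named list of envelope series.
#' @export
generate_emg <- function(com, gains_list, e0, noise_sd = 0,
                         config = model_config()) {
  if (noise_sd < 0) stop("envelope noise sd must be >= 0")
  out <- list()
  for (m in MUSCLES) {
    rec <- reconstruct_emg(gains_list[[m]], e0, com, config,
                           role = muscle_role(m))
    env <- rec$recon
    if (noise_sd > 0) env <- env + rnorm(length(env), 0, noise_sd)
    out[[m]] <- pmax(env, 0)
  }
  out
}

#' Which gains are identifiable for a given trajectory?
#'
#' A gain multiplying a regressor that is (after rectification masking)
#' essentially never expressed in the reconstruction over the fit window
#' cannot be recovered. A gain counts as identifiable when the L2 norm of
#' its masked regressor over the fit window exceeds `tol`, i.e., a unit
#' change of the gain changes the reconstruction appreciably.
#'
#' @param gains Named gain vector (the ground truth).
#' @param e0 Baseline.
#' @param com A [com_kinematics()] object.
#' @param config A [model_config()].
#' @param role Muscle role.
#' @param tol Sensitivity threshold (default 1e-2).
#' @return Named logical vector over the gains.
#' @export
gain_identifiability <- function(gains, e0, com, config = model_config(),
                                 role = c("plantar_flexor",
                                          "tibialis_anterior"),
                                 tol = 1e-2) {
  role <- match.arg(role)
  rec <- reconstruct_emg(gains, e0, com, config, role)
  reg <- model_regressors(com, config, role)
  idx <- fit_index(com$grid, config$fit_window)
  sens <- function(mat, mask) {
    apply(mat[idx, , drop = FALSE], 2, function(col) {
      sqrt(sum((col * mask[idx])^2))
    })
  }
  s <- c(sens(reg$bc, rec$bc_lin > 0), sens(reg$ant, rec$ant_lin > 0))
  out <- s[names(gains)] > tol
  names(out) <- names(gains)
  out
}

#' Which gains are recoverable to a given relative tolerance?
#'
#' Recovery of ground-truth gains from noiseless synthetic data is limited
#' by two things. Structurally, a gain whose (rectification-masked)
#' regressor is never expressed cannot move the reconstruction at all
#' (see [gain_identifiability()]). More subtly, the prime-gain penalty in
#' the fit cost shifts the global optimum away from the truth by a
#' predictable amount: linearising around the truth with fixed
#' rectification masks, the penalised optimum is
#' `truth - lambda (J'J + lambda P)^{-1} P truth`, with `J` the masked
#' regressor matrix over the fit window and `P` selecting the prime gains.
#' When prime regressors are nearly collinear this bias can exceed a
#' percent even though the gain is structurally identifiable. A gain is
#' reported recoverable at `rel_tol` when it is structurally identifiable,
#' strictly positive, and its predicted penalty bias is below
#' `rel_tol / 2` (leaving the other half of the budget to the optimiser).
#'
#' @inheritParams gain_identifiability
#' @param rel_tol Target relative recovery tolerance (default 0.01).
#' @return Named logical vector; attribute `"penalty_bias"` carries the
#'   predicted relative bias per gain.
#' @export
recoverable_gains <- function(gains, e0, com, config = model_config(),
                              role = c("plantar_flexor",
                                       "tibialis_anterior"),
                              rel_tol = 0.01) {
  role <- match.arg(role)
  structural <- gain_identifiability(gains, e0, com, config, role)
  rec <- reconstruct_emg(gains, e0, com, config, role)
  reg <- model_regressors(com, config, role)
  idx <- fit_index(com$grid, config$fit_window)
  nm <- names(gains)
  J <- cbind(
    reg$bc[idx, , drop = FALSE] * (rec$bc_lin[idx] > 0),
    reg$ant[idx, , drop = FALSE] * (rec$ant_lin[idx] > 0)
  )[, nm, drop = FALSE]
  P <- diag(as.numeric(nm %in% PRIME_GAINS))
  lam <- config$penalty_weight
  delta <- -lam * solve(crossprod(J) + lam * P, P %*% gains[nm])
  rel_bias <- as.numeric(delta) / ifelse(gains[nm] > 0, gains[nm], NA)
  out <- structural & gains[nm] > 0 &
    !is.na(rel_bias) & abs(rel_bias) < rel_tol / 2
  names(out) <- nm
  attr(out, "penalty_bias") <- setNames(rel_bias, nm)
  out
}

# One synthetic trial for a subject at a level: kinematics with per-trial
# amplitude jitter, envelopes from the subject's gains.
generate_trial <- function(subject_id, group, level, trial_index, gains,
                           noise, stepped = FALSE, onset_time = 1.0,
                           config = model_config(),
                           profile_params = PROFILE_DEFAULTS,
                           response_params = RESPONSE_DEFAULTS,
                           grid = analysis_grid(), raw_emg = FALSE,
                           raw_rate = 1000) {
  profile <- make_profile(level, profile_params)
  traj <- make_com_ankle(profile, response_params, grid)
  jit <- if (noise$kin_jitter_sd > 0) {
    1 + rnorm(1, 0, noise$kin_jitter_sd)
  } else {
    1
  }
  com_pos <- traj$com_pos * jit
  ankle <- traj$ankle_angle * jit
  pseudo <- list(grid = grid, rate = 1 / (grid[2] - grid[1]),
                 com_pos = com_pos, ankle_angle = ankle)
  com <- com_kinematics(pseudo, config$stiction_threshold)
  envs <- generate_emg(com, gains, noise$baseline, noise$envelope_sd, config)
  if (!raw_emg) {
    return(trial_recording(
      subject_id = subject_id, group = group, level = level,
      trial_index = trial_index, stepped = stepped, onset_time = onset_time,
      time_s = grid + onset_time, com_pos = com_pos, ankle_angle = ankle,
      emg = envs, emg_rate = pseudo$rate, kin_rate = pseudo$rate,
      emg_kind = "envelope"
    ))
  }
  # raw interference mode: white-noise carrier amplitude-modulated by the
  # envelope, stored at the EMG rate with kinematics interpolated onto the
  # same axis; exercises the band-pass/rectify/low-pass chain downstream.
  t_raw <- seq(grid[1], grid[length(grid)], by = 1 / raw_rate)
  raw <- lapply(envs, function(env) {
    approx(grid, env, xout = t_raw)$y * rnorm(length(t_raw))
  })
  trial_recording(
    subject_id = subject_id, group = group, level = level,
    trial_index = trial_index, stepped = stepped, onset_time = onset_time,
    time_s = t_raw + onset_time,
    com_pos = approx(grid, com_pos, xout = t_raw)$y,
    ankle_angle = approx(grid, ankle, xout = t_raw)$y,
    emg = raw, emg_rate = raw_rate, kin_rate = pseudo$rate,
    emg_kind = "raw"
  )
}

#' Generate a synthetic cohort
#'
#' Emulates the study design: two groups, four perturbation levels, eight
#' trials per level. Per-subject gains are drawn around the group
#' archetype (lognormal multipliers, sd `gain_sigma` on the log scale);
#' trials step (and are later excluded) independently with probability
#' `step_prob`. Fully deterministic given `seed`.
#'
#' @param n_per_group Subjects per group (>= 1).
#' @param seed Integer seed.
#' @param groups Named list mapping group label (`CP`, `TD`) to archetype
#'   name; default CP -> CP_like, TD -> TD_like.
#' @param noise A [noise_model()].
#' @param gain_sigma Log-scale spread of subject gains (default 0.25).
#' @param levels Levels to generate (default 1:4).
#' @param n_trials Trials per level (default 8).
#' @param step_prob Per-trial stepping probability (default 0.05).
#' @param dir Output directory; when `NULL` the cohort is returned
#'   in memory only.
#' @param config A [model_config()].
#' @param raw_emg When `TRUE`, trials carry 1 kHz raw interference EMG
#'   (envelope-modulated noise carrier) instead of envelopes, so the full
#'   filter chain is exercised downstream.
#' @return List with `trials` (list of [trial_recording()]),
#'   `ground_truth` (per subject: group and gain list), and, when written,
#'   `manifest_path` and `ground_truth_path`.
#' @export
generate_cohort <- function(n_per_group, seed,
                            groups = list(CP = "CP_like", TD = "TD_like"),
                            noise = noise_model(), gain_sigma = 0.25,
                            levels = 1:4, n_trials = 8, step_prob = 0.05,
                            dir = NULL, config = model_config(),
                            raw_emg = FALSE) {
  if (n_per_group < 1) stop("n_per_group must be >= 1")
  with_preserved_seed(seed, {
    trials <- list()
    ground_truth <- list()
    for (grp in names(groups)) {
      arche <- archetype_gains(groups[[grp]])
      for (i in seq_len(n_per_group)) {
        sid <- sprintf("%s%02d", grp, i)
        gains <- draw_subject_gains(arche, gain_sigma)
        ground_truth[[sid]] <- list(group = grp, gains = gains)
        for (lv in levels) {
          for (tr in seq_len(n_trials)) {
            stepped <- runif(1) < step_prob
            trials[[length(trials) + 1]] <- generate_trial(
              sid, grp, lv, tr, gains, noise,
              stepped = stepped, config = config, raw_emg = raw_emg
            )
          }
        }
      }
    }
    out <- list(trials = trials, ground_truth = ground_truth, seed = seed)
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      entries <- lapply(trials, function(rec) {
        rel <- sprintf("%s_L%d_T%02d.tsv", rec$subject_id, rec$level,
                       rec$trial_index)
        write_trial(rec, file.path(dir, rel))
        list(path = rel, subject_id = rec$subject_id, group = rec$group,
             level = rec$level, trial = rec$trial_index,
             onset_time_s = rec$onset_time, stepped = rec$stepped,
             emg_rate_hz = rec$emg_rate, kin_rate_hz = rec$kin_rate,
             emg_kind = rec$emg_kind)
      })
      out$manifest_path <- file.path(dir, "manifest.json")
      write_manifest(entries, out$manifest_path)
      gt <- lapply(ground_truth, function(s) {
        list(group = s$group, gains = lapply(s$gains, as.list))
      })
      out$ground_truth_path <- file.path(dir, "ground_truth.json")
      jsonlite::write_json(list(seed = seed, subjects = gt),
                           out$ground_truth_path,
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    out
  })
}
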