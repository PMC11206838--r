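test_that("profiles scale monotonically and differentiate consistently", {
  profs <- lapply(1:4, make_profile)
  pv <- vapply(profs, `[[`, 0, "peak_trans_vel")
  expect_true(all(diff(pv) > 0))
  rv <- vapply(profs, `[[`, 0, "peak_rot_vel")
  expect_true(all(diff(rv) > 0))
  # L1 = L2 < L3 = L4 translation displacement
  amp <- vapply(profs, `[[`, 0, "trans_amp")
  expect_equal(amp[1], amp[2])
  expect_lt(amp[2], amp[3])

  # start and end at rest
  for (p in profs) {
    expect_equal(p$trans_vel[1], 0)
    expect_equal(tail(p$trans_vel, 1), 0)
    expect_equal(p$rot_vel[1], 0)
    expect_equal(tail(p$rot_vel, 1), 0)
  }

  # closed-form derivative oracle on a dense grid; the pulse is C1 so the
  # comparison is made away from the two joins where curvature jumps
  p <- make_profile(2, rate = 10000)
  num <- differentiate(p$trans_disp, 10000)
  smooth <- p$time > 2e-4 & p$time < p$trans_dur - 2e-4
  expect_lt(max(abs(num - p$trans_vel)[smooth]), 1e-6)

  # zero amplitudes give the zero profile
  z <- make_profile(1, params = list(trans_disp_m = 0, trans_dur_s = 0.5,
                                     rot_amp_deg = 0, rot_delay_s = 0.15,
                                     rot_dur_s = 0.4))
  expect_equal(z$trans_disp, numeric(length(z$time)))
  expect_equal(z$rot_angle, numeric(length(z$time)))

  expect_error(make_profile(1, params = list(trans_disp_m = -0.1,
                                             trans_dur_s = 0.5,
                                             rot_amp_deg = 4,
                                             rot_delay_s = 0.15,
                                             rot_dur_s = 0.4)),
               "non-negative")
  expect_error(make_profile(7), "level")
})

count_sign_changes <- function(v, eps = 1e-6) {
  s <- sign(v)
  s[abs(v) < eps] <- 0
  s <- s[s != 0]
  sum(diff(s) != 0)
}

test_that("CoM trajectories reverse exactly once; ankle dorsiflexes early", {
  for (lv in 1:4) {
    traj <- make_com_ankle(make_profile(lv))
    grid <- traj$grid
    post <- grid > 0
    v <- differentiate(traj$com_pos, 100)
    expect_equal(count_sign_changes(v[post]), 1)
    # forward first, then net backward
    expect_gt(max(traj$com_pos), 0)
    expect_lt(traj$com_pos[length(grid)], 0)
    # ankle change crosses 0.5 degrees within the perturbation, early
    ank <- traj$ankle_angle - traj$ankle_angle[which(grid == 0)]
    t_cross <- grid[post][which(ank[post] >= 0.5)[1]]
    expect_lt(t_cross, 0.15)
  }

  zero <- make_profile(1, params = list(trans_disp_m = 0, trans_dur_s = 0.5,
                                        rot_amp_deg = 0, rot_delay_s = 0.15,
                                        rot_dur_s = 0.4))
  traj <- make_com_ankle(zero)
  expect_equal(traj$com_pos, numeric(length(traj$grid)))
  expect_equal(traj$ankle_angle, numeric(length(traj$grid)))

  # doubling translation amplitude strictly raises the forward peak
  p1 <- make_profile(2)
  p2 <- make_profile(2, params = modifyList(
    comfeedback:::PROFILE_DEFAULTS,
    list(trans_disp_m = 2 * comfeedback:::PROFILE_DEFAULTS$trans_disp_m)
  ))
  expect_gt(max(make_com_ankle(p2)$com_pos),
            max(make_com_ankle(p1)$com_pos))
})

test_that("generate_emg applies the forward model plus clipped noise", {
  fx <- synth_com(2)
  com <- fx$com
  zero_gains <- lapply(archetype_gains("TD_like"), function(g) g * 0)
  env <- generate_emg(com, zero_gains, e0 = 0.1, noise_sd = 0)
  for (m in names(env)) expect_equal(env[[m]], rep(0.1, length(com$grid)))

  expect_error(generate_emg(com, zero_gains, 0.1, noise_sd = -1), ">= 0")

  # TD-like with primes exactly zero: TA balance-correcting drive is
  # rectified away while the CoM moves forward, active after reversal
  td0 <- lapply(archetype_gains("TD_like"), function(g) {
    g[c("k_dp", "k_vp", "k_ap")] <- 0
    g
  })
  env <- generate_emg(com, td0, e0 = 0.05, noise_sd = 0)
  grid <- com$grid
  reversal <- grid[grid > 0][which(diff(sign(com$v[grid > 0])) != 0)[1]]
  early <- grid > 0.1 & grid < reversal - 0.05
  late <- grid > reversal + 0.2 & grid < reversal + 0.5
  expect_true(all(env$TA[early] <= 0.05 + 1e-12))
  expect_gt(mean(env$TA[late]), 0.05 + 0.01)
})

test_that("CP-like generation yields higher co-contraction than TD-like", {
  cfg <- model_config()
  noise <- noise_model(0.02, 0.05, 0)
  trial_for <- function(arche, seed) {
    comfeedback:::with_preserved_seed(seed, {
      comfeedback:::generate_trial("S", "TD", 2, 1,
                                   archetype_gains(arche), noise,
                                   config = cfg)
    })
  }
  seedlist <- c(4, 9, 23)
  for (s in seedlist) {
    cp <- preprocess_trial(trial_for("CP_like", s))
    td <- preprocess_trial(trial_for("TD_like", s))
    cci_cp <- cci_battery(cp)
    cci_td <- cci_battery(td)
    expect_true(all(cci_cp$value >= cci_td$value))
  }
})

test_that("cohort generation is seeded, counted, and byte-identical", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  c1 <- generate_cohort(2, seed = 7, levels = 1:2, n_trials = 2, dir = d1)
  c2 <- generate_cohort(2, seed = 7, levels = 1:2, n_trials = 2, dir = d2)
  expect_length(c1$trials, 2 * 2 * 2 * 2)
  f1 <- sort(list.files(d1))
  expect_identical(f1, sort(list.files(d2)))
  for (f in setdiff(f1, "manifest.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  # ground-truth sidecar re-readable and within bounds
  gt <- jsonlite::read_json(c1$ground_truth_path, simplifyVector = TRUE)
  gains <- unlist(gt$subjects[[1]]$gains)
  expect_true(all(gains >= 0 & gains <= 10))
  # manifest loads and covers every file
  m <- load_manifest(c1$manifest_path)
  expect_length(m$entries, length(c1$trials))

  # a different seed changes the data
  c3 <- generate_cohort(2, seed = 8, levels = 1:2, n_trials = 2)
  expect_false(identical(
    c1$trials[[1]]$emg$LG, c3$trials[[1]]$emg$LG
  ))
})

test_that("raw-EMG mode survives the full filter chain", {
  cfg <- model_config()
  noise <- noise_model(0, 0.05, 0)
  gains <- archetype_gains("CP_like")
  mk <- function(raw) {
    comfeedback:::with_preserved_seed(17, {
      comfeedback:::generate_trial("S", "CP", 2, 1, gains, noise,
                                   config = cfg, raw_emg = raw)
    })
  }
  raw_tr <- mk(TRUE)
  env_tr <- mk(FALSE)
  expect_identical(raw_tr$emg_kind, "raw")
  expect_equal(raw_tr$emg_rate, 1000)
  pp_raw <- preprocess_trial(raw_tr)   # runs filter_emg at 1 kHz
  pp_env <- preprocess_trial(env_tr)
  # after scaling, the demodulated envelope tracks the true one
  post <- pp_raw$grid > 0 & pp_raw$grid < 1
  for (m in c("LG", "TA")) {
    a <- scale_emg(list(pp_raw$emg_env[[m]]))$envelopes[[1]]
    b <- scale_emg(list(pp_env$emg_env[[m]]))$envelopes[[1]]
    expect_gt(cor(a[post], b[post]), 0.9)
  }
})

test_that("identifiability reporting distinguishes expressed gains", {
  fx <- synth_com(2)
  cfg <- model_config()
  g <- archetype_gains("CP_like")$LG
  idf <- gain_identifiability(g, 0.05, fx$com, cfg, "plantar_flexor")
  expect_true(all(idf[c("k_d", "k_v", "k_a", "k_s")]))
  rec <- recoverable_gains(g, 0.05, fx$com, cfg, "plantar_flexor")
  expect_true(all(rec[c("k_d", "k_v", "k_a", "k_s", "k_vp")]))
  bias <- attr(rec, "penalty_bias")
  expect_true(all(abs(bias[names(which(rec))]) < 0.005))
  # a gain that never contributes: zero out everything else so the
  # antagonist never rectifies on - with only k_dp on a forward-only
  # displacement, the ANT pathway stays dark pre-reversal
  d_only <- make_test_com(fx$com$grid, d = pmax(fx$com$d, 0))
  idf2 <- gain_identifiability(c(k_d = 1, k_dp = 0.1), 0.05, d_only,
                               cfg, "plantar_flexor")
  expect_false(idf2[["k_dp"]])
})
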