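test_that("gate_stiction opens at onset and closes at the angle threshold", {
  grid <- analysis_grid()
  a <- rnorm(211)

  # constant ankle: gate never closes, a_init = a for all t >= 0
  out <- gate_stiction(a, rep(2, 211), grid, 0.5)
  expect_equal(out[grid >= 0], a[grid >= 0])
  expect_equal(out[grid < 0], rep(0, sum(grid < 0)))

  # 5 deg/s ramp from onset with 0.5 deg threshold: closes at t = 0.1 s
  ramp <- 5 * pmax(grid, 0)
  out <- gate_stiction(a, ramp, grid, 0.5)
  open <- grid >= 0 & grid < 0.1 - 1e-9
  expect_equal(out[open], a[open])
  expect_equal(out[grid >= 0.1 - 1e-9], rep(0, sum(grid >= 0.1 - 1e-9)))

  expect_equal(gate_stiction(a, ramp, grid, 0), numeric(211))
  expect_error(gate_stiction(a, ramp, grid, -1), ">= 0")
})

test_that("reconstruct_emg evaluates the two rectified pathways", {
  grid <- analysis_grid()
  cfg <- model_config()
  zero <- make_test_com(grid)

  # all gains zero: constant e0
  r <- reconstruct_emg(c(k_d = 0), 0.1, zero, cfg, "plantar_flexor")
  expect_equal(r$recon, rep(0.1, 211))

  # constant forward displacement 0.05 m, k_d = 1/m: output 0.05
  # (constant pre-onset data makes the delay fill transparent)
  com <- make_test_com(grid, d = rep(0.05, 211))
  r <- reconstruct_emg(c(k_d = 1), 0, com, cfg, "plantar_flexor")
  expect_equal(r$recon, rep(0.05, 211))

  # sign bookkeeping: PF antagonist picks up backward velocity
  com <- make_test_com(grid, v = rep(-0.2, 211))
  r <- reconstruct_emg(c(k_vp = 1), 0.05, com, cfg, "plantar_flexor")
  expect_equal(r$ant, rep(0.2, 211))
  expect_equal(r$bc, rep(0.05, 211))

  # TA flips the signs: backward velocity drives its BC pathway
  r <- reconstruct_emg(c(k_v = 1), 0.05, com, cfg, "tibialis_anterior")
  expect_equal(r$bc, rep(0.25, 211))
  expect_equal(r$ant, rep(0, 211))

  expect_error(
    reconstruct_emg(c(k_s = 1), 0, com, cfg, "tibialis_anterior"),
    "stiction"
  )
  expect_error(reconstruct_emg(c(bogus = 1), 0, com, cfg), "unknown")
})

test_that("the 100 ms delay is an exact 10-sample shift at 100 Hz", {
  fx <- synth_com(2)
  com <- fx$com
  cfg <- model_config()
  r <- reconstruct_emg(c(k_v = 1), 0, com, cfg, "plantar_flexor")
  # shift oracle: rectified delayed velocity
  shifted <- c(rep(mean(com$v[com$grid < 0]), 10), head(com$v, -10))
  expect_equal(r$recon, pmax(shifted, 0))
})

test_that("TA balance-correcting drive is dark on monotone forward motion", {
  grid <- analysis_grid()
  d <- 0.03 * pmin(pmax(grid, 0) / 1.0, 1)
  com <- make_test_com(grid, d = d, v = pmax(differentiate(d, 100), 0),
                       a = abs(sg_acceleration(differentiate(d, 100), 100)))
  cfg <- model_config()
  r <- reconstruct_emg(c(k_d = 2, k_v = 2, k_a = 2), 0, com, cfg,
                       "tibialis_anterior")
  expect_equal(r$bc, rep(0, 211))
})

test_that("model_cost equals the brute-force sum plus the prime penalty", {
  fx <- synth_com(2)
  com <- fx$com
  cfg <- model_config()
  gains <- archetype_gains("TD_like")$LG
  rec <- reconstruct_emg(gains, 0.05, com, cfg, "plantar_flexor")

  # measured == reconstruction with zero primes: zero cost
  g0 <- gains
  g0[c("k_dp", "k_vp", "k_ap")] <- 0
  rec0 <- reconstruct_emg(g0, 0.05, com, cfg, "plantar_flexor")
  expect_equal(model_cost(g0, 0.05, rec0$recon, com, cfg,
                          "plantar_flexor"), 0)

  # penalty-only: antagonist input never positive -> k_vp contributes
  # nothing but its penalty (forward-only velocity, PF role)
  grid <- com$grid
  vmono <- make_test_com(grid, v = rep(0.1, 211))
  g <- c(k_v = 1, k_vp = 2)
  recm <- reconstruct_emg(g, 0, vmono, cfg, "plantar_flexor")
  expect_equal(model_cost(g, 0, recm$recon, vmono, cfg, "plantar_flexor"),
               1e-4 * 4)

  # brute-force per-sample oracle on random measured data
  set.seed(12)
  meas <- abs(rnorm(211, 0.2, 0.1))
  idx <- grid >= -0.5 - 1e-9 & grid <= 1.5 + 1e-9
  brute <- sum((rec$recon[idx] - meas[idx])^2) +
    1e-4 * sum(gains[c("k_dp", "k_vp", "k_ap")]^2)
  expect_equal(model_cost(gains, 0.05, meas, com, cfg, "plantar_flexor"),
               brute)
})

test_that("goodness_of_fit identities and textbook oracle", {
  grid <- analysis_grid()
  set.seed(13)
  m <- abs(rnorm(211, 0.3, 0.1))

  g <- goodness_of_fit(m, m, grid)
  expect_equal(g$r2, 1)
  expect_equal(g$vaf, 1)
  expect_equal(g$rmse, 0)

  g <- goodness_of_fit(m, m + 0.1, grid)
  expect_equal(g$r2, 1, tolerance = 1e-12)
  expect_lt(g$vaf, 1)
  expect_equal(g$rmse, 0.1, tolerance = 1e-12)

  r <- abs(rnorm(211, 0.3, 0.1))
  g <- goodness_of_fit(m, r, grid, c(0, 1.5))
  idx <- grid >= -1e-9 & grid <= 1.5 + 1e-9
  mm <- m[idx]; rr <- r[idx]
  expect_equal(g$r2, cor(mm, rr)^2, tolerance = 1e-12)
  expect_equal(g$vaf, 1 - sum((mm - rr)^2) / sum(mm^2), tolerance = 1e-12)
  expect_equal(g$rmse, sqrt(mean((mm - rr)^2)), tolerance = 1e-12)

  expect_warning(gc <- goodness_of_fit(rep(0.2, 211), r, grid),
                 "constant")
  expect_true(is.na(gc$r2))
  expect_false(is.na(gc$vaf))
})

test_that("cost_improvement is the percentage cost reduction", {
  expect_equal(cost_improvement(2, 2), 0)
  expect_equal(cost_improvement(1, 0.8), 20)
  expect_error(cost_improvement(0, 0), "positive")
})

test_that("fit_gains drives gains to zero for featureless EMG and nests", {
  fx <- synth_com(2)
  com <- fx$com
  meas <- rep(0.05, 211)
  fit <- suppressWarnings(
    fit_gains(meas, com, model_config(), "plantar_flexor")
  )
  expect_lt(max(fit$gains), 1e-4)
  expect_equal(fit$e0, 0.05)
  expect_true(all(c("k_d", "k_v") %in% fit$at_bound))  # at the 0 bound

  # extended cost <= simple cost on a nontrivial signal
  set.seed(14)
  meas <- pmax(fx$processed$emg_env$LG + rnorm(211, 0, 0.02), 0)
  ext <- fit_gains(meas, com, model_config(variant = "extended"),
                   "plantar_flexor")
  sim <- fit_gains(meas, com, model_config(variant = "simple"),
                   "plantar_flexor")
  expect_lte(ext$cost, sim$cost + 1e-12)
  expect_true(all(sim$gains[c("k_dp", "k_vp", "k_ap")] == 0))
  expect_gte(cost_improvement(sim$cost, ext$cost), 0)

  # determinism: same config seed, same answer
  ext2 <- fit_gains(meas, com, model_config(variant = "extended"),
                    "plantar_flexor")
  expect_identical(ext$gains, ext2$gains)
})
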