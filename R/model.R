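# Sensorimotor response model.
#
# Measured EMG envelopes are reconstructed as delayed linear feedback of
# CoM kinematics through two half-wave rectified pathways. For a plantar
# flexor (LG, MG, SOL):
#
#   EMG_recon(t) = | e0 + k_d d(t-tau) + k_v v(t-tau) + k_a a(t-tau)
#                       + k_s a_init(t-tau) |_+        (balance correcting)
#                + | k_d' (-d) + k_v' (-v) + k_a' (-a) |_+   (antagonistic)
#
# For tibialis anterior the signs of d, v, a are flipped in both pathways
# and there is no stiction term (the muscle is shortened first, abolishing
# the short-range-stiffness burst). tau = 100 ms throughout; |x|_+ is the
# positive part, representing excitatory drive to the motor pool. Gains are
# bounded in [0, 10] (per-unit: /m, s/m, s^2/m) and fitted by penalised
# least squares: squared reconstruction error over the fit window plus
# 1e-4 times the squared antagonistic ("prime") gains, which discourages
# antagonistic drive unless it clearly improves the fit.

PF_GAINS <- c("k_d", "k_v", "k_a", "k_s", "k_dp", "k_vp", "k_ap")
TA_GAINS <- c("k_d", "k_v", "k_a", "k_dp", "k_vp", "k_ap")
PRIME_GAINS <- c("k_dp", "k_vp", "k_ap")

#' Model configuration
#'
#' @param tau Feedback delay in seconds (default 0.100); must be an integer
#'   number of samples at the analysis rate.
#' @param bounds Upper bound applied to every gain (default 10; lower bound
#'   is 0). May be a single number or a named vector over gain names.
#' @param penalty_weight Weight on squared prime gains in the cost
#'   (default 1e-4).
#' @param stiction_threshold Ankle-angle change in degrees closing the
#'   stiction gate (default 0.5).
#' @param fit_window Cost window in seconds relative to onset
#'   (default `c(-0.5, 1.5)`).
#' @param gof_window Goodness-of-fit window (default `c(0, 1.5)`).
#' @param variant `"extended"` (both pathways) or `"simple"` (prime gains
#'   pinned at zero).
#' @param n_starts Number of multi-start optimisations (default 8).
#' @param seed Seed for the randomised starts (default 1).
#' @return A `model_config` list.
#' @export
model_config <- function(tau = 0.100, bounds = 10, penalty_weight = 1e-4,
                         stiction_threshold = 0.5,
                         fit_window = c(-0.5, 1.5), gof_window = c(0, 1.5),
                         variant = c("extended", "simple"),
                         n_starts = 8, seed = 1) {
  variant <- match.arg(variant)
  if (stiction_threshold < 0) stop("stiction_threshold must be >= 0")
  structure(
    list(tau = tau, bounds = bounds, penalty_weight = penalty_weight,
         stiction_threshold = stiction_threshold, fit_window = fit_window,
         gof_window = gof_window, variant = variant,
         n_starts = n_starts, seed = seed),
    class = "model_config"
  )
}

muscle_role <- function(muscle) {
  if (muscle %in% PLANTAR_FLEXORS) "plantar_flexor" else "tibialis_anterior"
}

gain_names <- function(role, variant = "extended") {
  nm <- if (role == "plantar_flexor") PF_GAINS else TA_GAINS
  if (variant == "simple") setdiff(nm, PRIME_GAINS) else nm
}

#' Stiction gating of CoM acceleration
#'
#' Returns a copy of the acceleration that equals `a_com` from perturbation
#' onset until the ankle angle has changed by `threshold` degrees from its
#' onset value, and zero elsewhere (including before onset). The gated
#' signal models the initial spindle burst associated with short-range
#' stiffness, which is released once the ankle has rotated through roughly
#' half a degree.
#'
#' @param a_com CoM acceleration series.
#' @param ankle_angle Ankle angle series (deg) on the same grid.
#' @param grid Time axis (s), onset at 0.
#' @param threshold Gate-closing ankle change in degrees (default 0.5).
#' @return Gated acceleration series.
#' @export
gate_stiction <- function(a_com, ankle_angle, grid, threshold = 0.5) {
  if (threshold < 0) stop("stiction threshold must be >= 0")
  n <- length(grid)
  stopifnot(length(a_com) == n, length(ankle_angle) == n)
  out <- numeric(n)
  post <- which(grid >= 0)
  if (!length(post)) return(out)
  i0 <- post[1]
  change <- abs(ankle_angle - ankle_angle[i0])
  closed <- post[change[post] >= threshold]
  gate_end <- if (length(closed)) closed[1] - 1L else n
  if (gate_end >= i0) {
    idx <- i0:gate_end
    out[idx] <- a_com[idx]
  }
  out
}

# Shift a regressor by n_tau samples (delay); samples that would need data
# from before the recording are filled with the channel's quiet-stance
# (pre-onset) mean, which is ~0 by construction.
delay_shift <- function(x, n_tau, grid) {
  if (n_tau == 0) return(x)
  fill <- mean(x[grid < 0])
  c(rep(fill, n_tau), x[seq_len(length(x) - n_tau)])
}

resolve_bound <- function(bounds, names) {
  if (length(bounds) == 1 && is.null(names(bounds))) {
    setNames(rep(bounds, length(names)), names)
  } else {
    b <- bounds[names]
    if (any(is.na(b))) stop("bounds must cover all gains")
    setNames(as.numeric(b), names)
  }
}

# Delayed, signed regressor matrices for one muscle role. Returns BC and
# ANT regressor matrices (columns named by gain) on the full grid.
model_regressors <- function(com, config, role) {
  n_tau_f <- config$tau * com$rate
  n_tau <- as.integer(round(n_tau_f))
  if (abs(n_tau_f - n_tau) > 1e-6) {
    stop("tau must be an integer number of samples at the analysis rate")
  }
  D <- delay_shift(com$d, n_tau, com$grid)
  V <- delay_shift(com$v, n_tau, com$grid)
  A <- delay_shift(com$a, n_tau, com$grid)
  if (role == "plantar_flexor") {
    Ai <- delay_shift(com$a_init, n_tau, com$grid)
    bc <- cbind(k_d = D, k_v = V, k_a = A, k_s = Ai)
    ant <- cbind(k_dp = -D, k_vp = -V, k_ap = -A)
  } else {
    bc <- cbind(k_d = -D, k_v = -V, k_a = -A)
    ant <- cbind(k_dp = D, k_vp = V, k_ap = A)
  }
  list(bc = bc, ant = ant)
}

#' Reconstruct an EMG envelope from feedback gains
#'
#' Forward evaluation of the delayed CoM feedback model for one muscle.
#'
#' @param gains Named numeric vector of gains (`k_d`, `k_v`, `k_a`,
#'   `k_s` for plantar flexors, and prime gains `k_dp`, `k_vp`, `k_ap`).
#'   Missing names are treated as 0, but `k_s` must not be supplied for
#'   tibialis anterior.
#' @param e0 Baseline activity (normalised EMG units).
#' @param com A [com_kinematics()] object.
#' @param config A [model_config()].
#' @param role `"plantar_flexor"` or `"tibialis_anterior"`.
#' @return List with `recon`, `bc` (balance-correcting contribution) and
#'   `ant` (antagonistic contribution), each a series on `com$grid`.
#' @export
reconstruct_emg <- function(gains, e0, com, config,
                            role = c("plantar_flexor", "tibialis_anterior")) {
  role <- match.arg(role)
  unknown <- setdiff(names(gains), PF_GAINS)
  if (length(unknown)) {
    stop("unknown gain name(s): ", paste(unknown, collapse = ", "))
  }
  if (role == "tibialis_anterior" && "k_s" %in% names(gains)) {
    stop("no stiction gain is defined for tibialis anterior")
  }
  full <- setNames(numeric(length(PF_GAINS)), PF_GAINS)
  full[names(gains)] <- gains
  reg <- model_regressors(com, config, role)
  bc_lin <- e0 + drop(reg$bc %*% full[colnames(reg$bc)])
  ant_lin <- drop(reg$ant %*% full[colnames(reg$ant)])
  bc <- pmax(bc_lin, 0)
  ant <- pmax(ant_lin, 0)
  list(recon = bc + ant, bc = bc, ant = ant,
       bc_lin = bc_lin, ant_lin = ant_lin)
}

#' Model cost
#'
#' Sum of squared differences between reconstructed and measured EMG over
#' the fit window, plus `penalty_weight` times the sum of squared prime
#' gains.
#'
#' @inheritParams reconstruct_emg
#' @param measured Measured envelope on `com$grid`.
#' @return Scalar cost.
#' @export
model_cost <- function(gains, e0, measured, com, config,
                       role = c("plantar_flexor", "tibialis_anterior")) {
  role <- match.arg(role)
  rec <- reconstruct_emg(gains, e0, com, config, role)
  idx <- fit_index(com$grid, config$fit_window)
  primes <- gains[intersect(names(gains), PRIME_GAINS)]
  sum((rec$recon[idx] - measured[idx])^2) +
    config$penalty_weight * sum(primes^2)
}

fit_index <- function(grid, window) {
  which(grid >= window[1] - 1e-9 & grid <= window[2] + 1e-9)
}

# Cost and analytic (sub)gradient for the optimiser, on precomputed
# regressors restricted to the fit window.
make_objective <- function(reg_bc, reg_ant, e0, measured, penalty,
                           prime_mask) {
  function(theta) {
    bc_lin <- e0 + drop(reg_bc %*% theta[colnames(reg_bc)])
    ant_lin <- if (ncol(reg_ant)) {
      drop(reg_ant %*% theta[colnames(reg_ant)])
    } else {
      numeric(length(bc_lin))
    }
    recon <- pmax(bc_lin, 0) + pmax(ant_lin, 0)
    r <- recon - measured
    cost <- sum(r^2) + penalty * sum(theta[prime_mask]^2)
    g <- numeric(length(theta))
    names(g) <- names(theta)
    wb <- 2 * r * (bc_lin > 0)
    g[colnames(reg_bc)] <- drop(crossprod(reg_bc, wb))
    if (ncol(reg_ant)) {
      wa <- 2 * r * (ant_lin > 0)
      g[colnames(reg_ant)] <- g[colnames(reg_ant)] +
        drop(crossprod(reg_ant, wa))
    }
    g[prime_mask] <- g[prime_mask] + 2 * penalty * theta[prime_mask]
    list(cost = cost, grad = g)
  }
}

#' Fit feedback gains to a measured envelope
#'
#' Bounded multi-start quasi-Newton minimisation of [model_cost()]. The
#' baseline `e0` is not optimised: it is the mean of the measured envelope
#' over the half second before onset. The cost is piecewise smooth (the
#' rectifications introduce kinks), so several starts are used — the
#' origin, the centre of the gain box, and seeded random points in the
#' lower part of the box — and the best local solution is kept.
#'
#' @param measured Measured (scaled) envelope on the analysis grid.
#' @param com A [com_kinematics()] object.
#' @param config A [model_config()]; `config$variant` selects the extended
#'   model (both pathways) or the simple model (prime gains fixed at 0).
#' @param role `"plantar_flexor"` or `"tibialis_anterior"`.
#' @return A `feedback_fit` list: `gains` (named vector, zero entries for
#'   prime gains under the simple variant), `e0`, `cost`, `recon`/`bc`/`ant`
#'   series, goodness of fit (`r2`, `vaf`, `rmse` over the GOF window),
#'   `at_bound` (gains within 1e-6 of a box bound), `convergence`.
#' @export
fit_gains <- function(measured, com, config = model_config(),
                      role = c("plantar_flexor", "tibialis_anterior")) {
  role <- match.arg(role)
  grid <- com$grid
  e0 <- mean(measured[grid >= -0.5 - 1e-9 & grid < 0])
  nm <- gain_names(role, config$variant)
  ub <- resolve_bound(config$bounds, nm)
  reg <- model_regressors(com, config, role)
  idx <- fit_index(grid, config$fit_window)
  reg_bc <- reg$bc[idx, intersect(colnames(reg$bc), nm), drop = FALSE]
  ant_cols <- intersect(colnames(reg$ant), nm)
  reg_ant <- reg$ant[idx, ant_cols, drop = FALSE]
  prime_mask <- nm %in% PRIME_GAINS
  obj <- make_objective(reg_bc, reg_ant, e0, measured[idx],
                        config$penalty_weight, prime_mask)

  starts <- list(
    setNames(rep(0, length(nm)), nm),
    ub / 2
  )
  n_rand <- max(0, config$n_starts - length(starts))
  if (n_rand > 0) {
    rand <- with_preserved_seed(config$seed, {
      lapply(seq_len(n_rand), function(i) {
        setNames(runif(length(nm), 0, pmin(ub, 2)), nm)
      })
    })
    starts <- c(starts, rand)
  }

  best <- NULL
  for (s in starts) {
    fit <- stats::optim(
      par = s,
      fn = function(th) obj(th)$cost,
      gr = function(th) obj(th)$grad,
      method = "L-BFGS-B", lower = rep(0, length(nm)), upper = ub,
      control = list(maxit = 500, factr = 1e3)
    )
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  # polish from the best point
  best <- stats::optim(
    par = best$par, fn = function(th) obj(th)$cost,
    gr = function(th) obj(th)$grad,
    method = "L-BFGS-B", lower = rep(0, length(nm)), upper = ub,
    control = list(maxit = 1000, factr = 10)
  )

  gains <- setNames(numeric(length(gain_names(role, "extended"))),
                    gain_names(role, "extended"))
  gains[nm] <- best$par
  rec <- reconstruct_emg(gains, e0, com, config, role)
  gof <- goodness_of_fit(measured, rec$recon, grid, config$gof_window)
  at_bound <- names(which(best$par <= 1e-6 | ub - best$par <= 1e-6))
  structure(
    list(gains = gains, e0 = e0, cost = best$value, role = role,
         variant = config$variant, recon = rec$recon, bc = rec$bc,
         ant = rec$ant, r2 = gof$r2, vaf = gof$vaf, rmse = gof$rmse,
         at_bound = at_bound, convergence = best$convergence),
    class = "feedback_fit"
  )
}

#' @export
print.feedback_fit <- function(x, ...) {
  cat(sprintf("<feedback_fit> %s, %s model\n", x$role, x$variant))
  print(round(x$gains, 4))
  cat(sprintf("  e0 = %.4f, cost = %.5g, r2 = %.3f, VAF = %.3f, RMSE = %.4f\n",
              x$e0, x$cost, x$r2, x$vaf, x$rmse))
  if (length(x$at_bound)) {
    cat("  at bound:", paste(x$at_bound, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Goodness of fit between measured and reconstructed EMG
#'
#' `r2` is the squared Pearson correlation; `vaf` is the uncentred
#' coefficient of determination `1 - sum((m - r)^2) / sum(m^2)`; `rmse` is
#' the root mean squared error. All over `window` (default onset to 1.5 s).
#'
#' @param measured,recon Series on `grid`.
#' @param grid Time axis (s).
#' @param window Two-element window (s).
#' @return List with `r2`, `vaf`, `rmse`. `r2` is `NA` (with a warning)
#'   when the measured signal is constant.
#' @export
goodness_of_fit <- function(measured, recon, grid, window = c(0, 1.5)) {
  idx <- fit_index(grid, window)
  m <- measured[idx]
  r <- recon[idx]
  r2 <- if (sd(m) == 0 || sd(r) == 0) {
    warning("constant signal in GOF window: r2 undefined")
    NA_real_
  } else {
    stats::cor(m, r)^2
  }
  list(
    r2 = r2,
    vaf = 1 - sum((m - r)^2) / sum(m^2),
    rmse = sqrt(mean((m - r)^2))
  )
}

#' Cost improvement of the extended over the simple model
#'
#' Percentage reduction in fit cost when the antagonistic pathway is added:
#' `100 * (simple - extended) / simple`.
#'
#' @param simple_cost,extended_cost Achieved minimum costs.
#' @return Percentage (non-negative when both fits converged, since the
#'   simple model is nested in the extended one).
#' @export
cost_improvement <- function(simple_cost, extended_cost) {
  if (simple_cost <= 0) {
    stop("degenerate simple fit: cost must be positive")
  }
  100 * (simple_cost - extended_cost) / simple_cost
}

# Evaluate code with a temporary RNG seed, restoring the caller's RNG state.
with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
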