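# Time-binned reactive activity and kinematics.
#
# Reactive EMG is the scaled envelope minus its mean over the 100 ms before
# onset. It is summarised in three bins chosen around the typical response
# sequence to a combined translation + toe-up rotation: Z1 = [0, 150) ms
# (little activity: slow platform onset plus neural delay), Z2 = [150, 250)
# ms (first plantar flexor peak), Z3 = [250, 400) ms (switch to tibialis
# anterior). Kinematic channels use the same bins shifted 100 ms earlier
# ([0, 50), [50, 150), [150, 300) ms), because the kinematics are the
# sensory input that precedes the muscle response by the neural delay.

EMG_BIN_EDGES <- c(0, 0.150, 0.250, 0.400)
KIN_BIN_EDGES <- c(0, 0.050, 0.150, 0.300)

#' Baseline-subtracted (reactive) EMG
#'
#' @param env Envelope series.
#' @param grid Time axis (s), onset at 0; must cover `[-0.1, 0)`.
#' @return `env` minus the scalar mean of its pre-onset 100 ms; may be
#'   negative.
#' @export
reactive_emg <- function(env, grid) {
  pre <- grid >= -0.1 - 1e-9 & grid < 0
  if (!any(pre) || min(grid) > -0.1 + 1e-9) {
    stop("grid must cover the 100 ms before onset")
  }
  env - mean(env[pre])
}

#' Per-bin means of a series
#'
#' Arithmetic mean of the samples whose time stamp falls in each half-open
#' bin `[start, end)`. Membership is by time comparison, not index
#' arithmetic, so any uniform grid works.
#'
#' @param x Series on `grid`.
#' @param grid Time axis (s).
#' @param edges Bin edges (length `nbins + 1`, increasing).
#' @return Named numeric vector of bin means (`Z1`, `Z2`, ...).
#' @export
bin_means <- function(x, grid, edges = EMG_BIN_EDGES) {
  stopifnot(length(edges) >= 2, all(diff(edges) > 0))
  nb <- length(edges) - 1
  out <- setNames(numeric(nb), paste0("Z", seq_len(nb)))
  for (b in seq_len(nb)) {
    idx <- grid >= edges[b] - 1e-9 & grid < edges[b + 1] - 1e-9
    if (!any(idx)) {
      stop(sprintf("bin [%g, %g) contains no samples", edges[b], edges[b + 1]))
    }
    out[b] <- mean(x[idx])
  }
  out
}

#' Time-bin summary of one processed (trial-averaged) response
#'
#' Reactive EMG bin means per muscle (EMG bins) and kinematic bin means for
#' CoM displacement/velocity/acceleration and ankle angle change /
#' velocity / acceleration (bins shifted 100 ms earlier). Ankle angle is
#' re-referenced to its onset value.
#'
#' @param processed A `processed_trial` (scaled, typically trial-averaged).
#' @param com A [com_kinematics()] object for the same response; computed
#'   from `processed` when omitted.
#' @param emg_edges,kin_edges Bin edges (defaults: the standard Z1-Z3 sets).
#' @return A data.frame with columns `channel`, `bin`, `value`.
#' @export
timebin_summary <- function(processed, com = NULL,
                            emg_edges = EMG_BIN_EDGES,
                            kin_edges = KIN_BIN_EDGES) {
  grid <- processed$grid
  if (is.null(com)) com <- com_kinematics(processed)
  rows <- list()
  for (m in MUSCLES) {
    vals <- bin_means(reactive_emg(processed$emg_env[[m]], grid), grid,
                      emg_edges)
    rows[[m]] <- data.frame(channel = m, bin = names(vals), value = vals)
  }
  i0 <- which.min(abs(grid))
  kin <- list(
    com_d = com$d, com_v = com$v, com_a = com$a,
    ankle_angle = com$ankle - com$ankle[i0],
    ankle_v = com$ankle_v, ankle_a = com$ankle_a
  )
  for (ch in names(kin)) {
    vals <- bin_means(kin[[ch]], grid, kin_edges)
    rows[[ch]] <- data.frame(channel = ch, bin = names(vals), value = vals)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
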