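# Co-contraction index.
#
# CCI between tibialis anterior and a plantar flexor is the mean, over the
# frames of a window, of the pointwise minimum of the two scaled envelopes:
# near zero when the muscles are active at different times, large when they
# are active together. Computed on filtered and scaled EMG without baseline
# subtraction, over two windows: the reactive window [0, 0.4) s and the
# model window [-0.5, 1.5) s.

CCI_WINDOWS <- list(short = c(0, 0.4), long = c(-0.5, 1.5))

#' Co-contraction index of two envelopes
#'
#' @param emg_a,emg_b Scaled envelopes on the same grid.
#' @param grid Time axis (s), onset at 0.
#' @param window Two-element window (s); frames are samples with time in
#'   `[window[1], window[2])`.
#' @return Scalar CCI (normalised EMG units, >= 0 for non-negative input).
#' @export
cci <- function(emg_a, emg_b, grid, window = c(0, 0.4)) {
  if (length(emg_a) != length(grid) || length(emg_b) != length(grid)) {
    stop("envelopes and grid have mismatched lengths")
  }
  idx <- grid >= window[1] - 1e-9 & grid < window[2] - 1e-9
  if (!any(idx)) stop("empty CCI window")
  mean(pmin(emg_a[idx], emg_b[idx]))
}

#' CCI battery for one processed response
#'
#' All three plantar flexor-TA pairs crossed with the short and long
#' windows: six values.
#'
#' @param processed A `processed_trial` with scaled envelopes.
#' @param windows Named list of windows (default `CCI_WINDOWS`).
#' @return Data.frame with columns `pair`, `window`, `value`.
#' @export
cci_battery <- function(processed, windows = CCI_WINDOWS) {
  ta <- processed$emg_env$TA
  rows <- list()
  for (pf in PLANTAR_FLEXORS) {
    for (w in names(windows)) {
      rows[[paste(pf, w)]] <- data.frame(
        pair = paste0(pf, "-TA"), window = w,
        value = cci(processed$emg_env[[pf]], ta, processed$grid, windows[[w]])
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
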