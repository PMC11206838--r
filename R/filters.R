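# IIR design and zero-phase filtering.
#
# Digital Butterworth filters are designed by the classic analog-prototype /
# bilinear-transform route and applied as a cascade of second-order sections
# (biquads), which keeps high-order band-pass designs numerically stable.
# Zero-phase application (forward-backward) uses odd signal extension and
# steady-state initial conditions per section, so constant inputs produce the
# filter's DC response exactly (no start-up transient).

butter_prototype_poles <- function(n) {
  k <- seq_len(n)
  exp(1i * pi * (2 * k + n - 1) / (2 * n))
}

# Bilinear transform of an analog zero/pole/gain triple sampled at fs.
# Zeros at infinity map to z = -1.
bilinear_zpk <- function(z, p, k, fs) {
  fs2 <- 2 * fs
  degree <- length(p) - length(z)
  stopifnot(degree >= 0)
  zd <- (fs2 + z) / (fs2 - z)
  pd <- (fs2 + p) / (fs2 - p)
  kd <- k * Re(prod(fs2 - z) / prod(fs2 - p))
  zd <- c(zd, rep(-1 + 0i, degree))
  list(z = zd, p = pd, k = kd)
}

# Group conjugate pole/zero pairs into second-order sections.
# Poles are assumed to come in conjugate pairs (true for the even-order
# Butterworth designs used here).
zpk_to_sos <- function(z, p, k) {
  pair_up <- function(roots) {
    roots <- roots[order(-abs(Im(roots)), Re(roots))]
    pairs <- list()
    used <- rep(FALSE, length(roots))
    for (i in seq_along(roots)) {
    if (used[i]) next
      r <- roots[i]
      used[i] <- TRUE
      if (abs(Im(r)) > 1e-12) {
        j <- which(!used & abs(roots - Conj(r)) < 1e-8)[1]
        stopifnot(!is.na(j))
        used[j] <- TRUE
        pairs[[length(pairs) + 1]] <- c(r, Conj(r))
      } else {
        j <- which(!used & abs(Im(roots)) <= 1e-12)[1]
        if (is.na(j)) {
          pairs[[length(pairs) + 1]] <- c(r, 0i)
        } else {
          used[j] <- TRUE
          pairs[[length(pairs) + 1]] <- c(r, roots[j])
        }
      }
    }
    pairs
  }
  ppairs <- pair_up(p)
  zpairs <- pair_up(z)
  stopifnot(length(ppairs) == length(zpairs))
  n_sec <- length(ppairs)
  sos <- matrix(0, n_sec, 6)
  for (i in seq_len(n_sec)) {
    pp <- ppairs[[i]]
    zz <- zpairs[[i]]
    a <- Re(c(1, -(pp[1] + pp[2]), pp[1] * pp[2]))
    b <- Re(c(1, -(zz[1] + zz[2]), zz[1] * zz[2]))
    sos[i, ] <- c(b, a)
  }
  sos[1, 1:3] <- sos[1, 1:3] * k
  sos
}

#' Design a digital Butterworth filter as second-order sections
#'
#' @param n Filter order (per pass; a band-pass of order `n` has `2n` poles).
#' @param cutoff Cutoff frequency in Hz (length 1 for low-pass, length 2 for
#'   band-pass).
#' @param fs Sampling rate in Hz.
#' @param type `"low"` or `"band"`.
#' @return A matrix with one row per biquad section, columns
#'   `b0 b1 b2 a0 a1 a2`.
#' @keywords internal
butter_sos <- function(n, cutoff, fs, type = c("low", "band")) {
  type <- match.arg(type)
  if (any(cutoff <= 0) || any(cutoff >= fs / 2)) {
    stop("cutoff frequencies must lie strictly inside (0, fs/2)")
  }
  p <- butter_prototype_poles(n)
  fs2 <- 2 * fs
  warp <- function(f) fs2 * tan(pi * f / fs)
  if (type == "low") {
    wc <- warp(cutoff[1])
    zpk <- list(z = complex(0), p = p * wc, k = wc^n)
  } else {
    stopifnot(length(cutoff) == 2, cutoff[1] < cutoff[2])
    w1 <- warp(cutoff[1]); w2 <- warp(cutoff[2])
    bw <- w2 - w1
    w0 <- sqrt(w1 * w2)
    ps <- p * bw / 2
    disc <- sqrt(ps^2 - w0^2)
    zpk <- list(z = rep(0 + 0i, n), p = c(ps + disc, ps - disc), k = bw^n)
  }
  d <- bilinear_zpk(zpk$z, zpk$p, zpk$k, fs)
  zpk_to_sos(d$z, d$p, d$k)
}

# Steady-state state vector (direct form II transposed) for unit step input,
# used to suppress start-up transients (same idea as scipy's lfilter_zi).
biquad_zi <- function(b, a) {
  A <- rbind(c(-a[2], 1), c(-a[3], 0))
  B <- c(b[2] - a[2] * b[1], b[3] - a[3] * b[1])
  solve(diag(2) - A, B)
}

biquad_filter <- function(b, a, x, zi = c(0, 0)) {
  n <- length(x)
  y <- numeric(n)
  z1 <- zi[1]; z2 <- zi[2]
  b0 <- b[1]; b1 <- b[2]; b2 <- b[3]; a1 <- a[2]; a2 <- a[3]
  for (i in seq_len(n)) {
    xi <- x[i]
    yi <- b0 * xi + z1
    z1 <- b1 * xi - a1 * yi + z2
    z2 <- b2 * xi - a2 * yi
    y[i] <- yi
  }
  y
}

sos_filter <- function(sos, x, zi_scale = NULL) {
  for (i in seq_len(nrow(sos))) {
    b <- sos[i, 1:3]; a <- sos[i, 4:6]
    zi <- if (is.null(zi_scale)) c(0, 0) else biquad_zi(b, a) * zi_scale
    x <- biquad_filter(b, a, x, zi)
    if (!is.null(zi_scale)) {
      # DC gain of this section times the boundary value drives the next one
      zi_scale <- zi_scale * sum(b) / sum(a)
    }
  }
  x
}

#' Zero-phase filtering of a signal through a biquad cascade
#'
#' Forward-backward application with odd extension at both ends and
#' steady-state initial conditions, squaring the magnitude response and
#' cancelling phase.
#'
#' @param sos Section matrix from [butter_sos()].
#' @param x Numeric signal.
#' @return Filtered signal, same length as `x`.
#' @keywords internal
sos_filtfilt <- function(sos, x) {
  n <- length(x)
  padlen <- min(n - 1L, 3L * (2L * nrow(sos) + 1L) * 3L)
  if (padlen < 1) stop("signal too short to filter")
  ext <- c(
    2 * x[1] - x[seq(padlen + 1, 2)],
    x,
    2 * x[n] - x[seq(n - 1, n - padlen)]
  )
  y <- sos_filter(sos, ext, zi_scale = ext[1])
  y <- rev(y)
  y <- sos_filter(sos, y, zi_scale = y[1])
  y <- rev(y)
  y[seq(padlen + 1, padlen + n)]
}

#' Savitzky-Golay derivative filter
#'
#' Local least-squares polynomial differentiation: a polynomial of
#' `order` is fit to each window of `window` samples and its first
#' derivative evaluated at the window centre, scaled by the sampling rate.
#' Edge samples (the first and last `(window-1)/2`) are computed from
#' one-sided fits to the terminal window, so interior accuracy guarantees
#' do not extend to them.
#'
#' @param x Numeric signal on a uniform grid.
#' @param fs Sampling rate in Hz.
#' @param order Polynomial order (default 5).
#' @param window Window length in samples, odd (default 11).
#' @return The first derivative of `x`, in units of `x` per second.
#' @export
savgol_deriv <- function(x, fs, order = 5, window = 11) {
  n <- length(x)
  if (window %% 2 != 1) stop("window length must be odd")
  if (order >= window) stop("polynomial order must be below window length")
  if (n < window) stop(sprintf("need at least %d samples, got %d", window, n))
  half <- (window - 1L) %/% 2L
  pos <- seq(-half, half)
  A <- outer(pos, 0:order, `^`)
  # derivative-at-centre convolution coefficients: row 2 of the LS projector
  C <- solve(crossprod(A), t(A))
  d <- numeric(n)
  coef_center <- C[2, ]
  # embed() lays out windows reversed (newest sample first)
  d[seq(half + 1, n - half)] <-
    drop(stats::embed(x, window) %*% rev(coef_center))
  # one-sided fits for edges: fit the terminal window once, evaluate the
  # polynomial derivative at the edge positions
  edge_deriv <- function(idx, offset) {
    beta <- solve(crossprod(A), crossprod(A, x[idx]))
    vapply(offset, function(o) {
      j <- 1:order
      sum(beta[j + 1] * j * o^(j - 1))
    }, numeric(1))
  }
  d[1:half] <- edge_deriv(1:window, seq(-half, -1))
  d[(n - half + 1):n] <- edge_deriv((n - window + 1):n, seq(1, half))
  d * fs
}
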