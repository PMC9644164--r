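# Minimal digital-filter toolbox: Butterworth IIR design via the bilinear
# transform, zero-phase forward-backward filtering, windowed-sinc FIR
# low-pass design, and Savitzky-Golay smoothing.  These exist here because
# the package does not depend on an external signal-processing library;
# behaviour is pinned against reference implementations in the test suite.

#' Design a digital Butterworth filter
#'
#' Classic analog Butterworth prototype mapped to the z-domain with the
#' bilinear transform (with frequency pre-warping), returned as transfer
#' function coefficients.
#'
#' @param order filter order (>= 1).
#' @param cutoff cutoff frequency in Hz (the -3 dB point of a single pass).
#' @param fs sampling rate in Hz; `cutoff` must be below `fs / 2`.
#' @param type `"high"` or `"low"`.
#' @return list with numerator `b` and denominator `a` coefficients
#'   (length `order + 1`, `a[1] == 1`).
#' @export
butter_design <- function(order, cutoff, fs, type = c("high", "low")) {
  type <- match.arg(type)
  stopifnot(order >= 1, cutoff > 0, fs > 0)
  if (cutoff >= fs / 2) {
    stop("cutoff must be below the Nyquist frequency (fs/2)")
  }
  k <- seq_len(order)
  # analog low-pass prototype: poles on the unit circle, left half plane
  p <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  fs2 <- 2 * fs
  warped <- fs2 * tan(pi * cutoff / fs)          # pre-warped analog cutoff
  if (type == "low") {
    pa <- warped * p
    za <- complex(0)
    # H(s) = k / prod(s - p); unity DC gain
    ka <- Re(prod(-pa))
  } else {
    pa <- warped / p
    za <- rep(0 + 0i, order)
    ka <- 1                                       # unity gain at s -> Inf
  }
  # bilinear transform z = (2fs + s) / (2fs - s)
  pz <- (fs2 + pa) / (fs2 - pa)
  zz <- if (length(za)) (fs2 + za) / (fs2 - za) else complex(0)
  # pad zeros at z = -1 up to the pole count (low-pass case)
  zz <- c(zz, rep(-1 + 0i, length(pz) - length(zz)))
  kz <- ka * Re(prod(fs2 - za) / prod(fs2 - pa))
  b <- Re(poly_from_roots(zz)) * kz
  a <- Re(poly_from_roots(pz))
  list(b = b, a = a)
}

# expand prod (x - r_i) into monic polynomial coefficients, highest first
poly_from_roots <- function(r) {
  coefs <- 1 + 0i
  for (ri in r) coefs <- c(coefs, 0) - c(0, coefs) * ri
  coefs
}

# direct-form II transposed IIR filter with initial conditions
iir_filter <- function(b, a, x, zi = NULL) {
  nfilt <- max(length(a), length(b))
  b <- c(b, rep(0, nfilt - length(b)))
  a <- c(a, rep(0, nfilt - length(a)))
  if (a[1] != 1) {
    b <- b / a[1]
    a <- a / a[1]
  }
  n <- length(x)
  y <- numeric(n)
  z <- if (is.null(zi)) numeric(nfilt - 1) else zi
  for (t in seq_len(n)) {
    xt <- x[t]
    yt <- b[1] * xt + z[1]
    if (nfilt > 2) {
      for (j in seq_len(nfilt - 2)) {
        z[j] <- b[j + 1] * xt - a[j + 1] * yt + z[j + 1]
      }
    }
    z[nfilt - 1] <- b[nfilt] * xt - a[nfilt] * yt
    y[t] <- yt
  }
  y
}

# steady-state initial conditions for a unit step (cf. lfilter_zi):
# makes filtfilt transients vanish for locally constant ends
iir_step_state <- function(b, a) {
  nfilt <- max(length(a), length(b))
  b <- c(b, rep(0, nfilt - length(b)))
  a <- c(a, rep(0, nfilt - length(a)))
  ydc <- sum(b) / sum(a)
  z <- numeric(nfilt - 1)
  z[nfilt - 1] <- b[nfilt] - a[nfilt] * ydc
  if (nfilt > 2) {
    for (j in rev(seq_len(nfilt - 2))) {
      z[j] <- z[j + 1] + b[j + 1] - a[j + 1] * ydc
    }
  }
  z
}

#' Zero-phase (forward-backward) IIR filtering
#'
#' Applies the filter twice, forward and reverse, so the net phase response
#' is zero and the amplitude response is the squared single-pass magnitude.
#' Edges are stabilized by odd reflection padding and step-matched initial
#' conditions.
#'
#' @param b,a transfer-function coefficients, e.g. from [butter_design()].
#' @param x numeric vector.
#' @return filtered vector, same length as `x`.
#' @export
filtfilt <- function(b, a, x) {
  n <- length(x)
  nfilt <- max(length(a), length(b))
  padlen <- min(n - 1, 3 * nfilt)
  if (padlen < 1) stop("signal too short for filtfilt")
  # odd extension about the end points
  pre <- 2 * x[1] - x[seq(padlen + 1, 2)]
  post <- 2 * x[n] - x[seq(n - 1, n - padlen)]
  ext <- c(pre, x, post)
  zi <- iir_step_state(b, a)
  y <- iir_filter(b, a, ext, zi * ext[1])
  y <- rev(y)
  y <- iir_filter(b, a, y, zi * y[1])
  y <- rev(y)
  y[seq(padlen + 1, padlen + n)]
}

#' Windowed-sinc low-pass FIR taps
#'
#' Blackman-windowed ideal low-pass impulse response, normalized to unit DC
#' gain; used for anti-alias filtering before decimation.
#'
#' @param ntaps odd number of taps.
#' @param cutoff cutoff as a fraction of the Nyquist frequency, in (0, 1).
#' @return numeric vector of taps summing to 1.
#' @export
fir_lowpass <- function(ntaps, cutoff) {
  stopifnot(ntaps %% 2 == 1, cutoff > 0, cutoff < 1)
  m <- (ntaps - 1) / 2
  k <- seq(-m, m)
  h <- cutoff * sinc(cutoff * k)
  w <- 0.42 + 0.5 * cos(pi * k / m) + 0.08 * cos(2 * pi * k / m)
  h <- h * w
  h / sum(h)
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# symmetric FIR applied with zero phase; edges by reflection
fir_filter_sym <- function(h, x) {
  m <- (length(h) - 1) / 2
  n <- length(x)
  if (n < 2) return(x)
  mm <- min(m, n - 1)
  pre <- x[seq(mm + 1, 2)]
  post <- x[seq(n - 1, n - mm)]
  if (mm < m) {
    pre <- c(rep(x[1], m - mm), pre)
    post <- c(post, rep(x[n], m - mm))
  }
  ext <- c(pre, x, post)
  y <- stats::filter(ext, h, method = "convolution", sides = 2)
  as.numeric(y[seq(m + 1, m + n)])
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing with a symmetric window. The
#' first and last half-windows are handled by evaluating the polynomial
#' fitted to the boundary window (polynomial extension), not by shrinking
#' the window.
#'
#' @param x numeric vector.
#' @param window odd window length in samples, `<= length(x)`.
#' @param order polynomial order (`order < window`). Order 1 on a symmetric
#'   window is identical to a moving average in the interior.
#' @return smoothed vector.
#' @export
savgol_smooth <- function(x, window, order = 1) {
  stopifnot(window %% 2 == 1, order >= 0)
  if (window == 1) return(x)          # degenerate window: no smoothing
  stopifnot(order < window)
  n <- length(x)
  if (window > n) stop("Savitzky-Golay window longer than the signal")
  m <- (window - 1) / 2
  V <- outer(seq(-m, m), 0:order, `^`)
  H <- V %*% solve(crossprod(V), t(V))     # projection onto the poly space
  mid <- H[m + 1, ]
  y <- fir_filter_sym(rev(mid), x)         # symmetric, rev() is a no-op
  # boundary windows: project and keep the outer halves
  head_fit <- H %*% x[seq_len(window)]
  tail_fit <- H %*% x[seq(n - window + 1, n)]
  y[seq_len(m)] <- head_fit[seq_len(m)]
  y[seq(n - m + 1, n)] <- tail_fit[seq(m + 2, window)]
  y
}

# best rational approximation p/q to x with q <= max_den (continued fractions)
rational_approx <- function(x, max_den = 10000L, tol = 1e-9) {
  p0 <- 0; q0 <- 1; p1 <- 1; q1 <- 0
  r <- x
  repeat {
    a <- floor(r)
    p2 <- a * p1 + p0
    q2 <- a * q1 + q0
    if (q2 > max_den) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(x - p1 / q1) < tol * max(1, abs(x))) break
    if (abs(r - a) < 1e-14) break
    r <- 1 / (r - a)
  }
  c(num = p1, den = q1)
}
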