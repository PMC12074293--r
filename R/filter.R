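# IIR filtering primitives. No DSP package ships with the target
# environment, so Butterworth design (bilinear transform of the analog
# prototype) and zero-phase application are implemented here and verified
# in the test suite against the closed-form magnitude response.

# expand a monic polynomial from its roots; returns real coefficients,
# highest degree first (roots come in conjugate pairs)
poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (rt in r) p <- c(p, 0) - c(0, p * rt)
  re <- Re(p)
  if (max(abs(Im(p))) > 1e-8 * max(1, max(abs(re)))) {
    stop("polynomial expansion produced complex coefficients", call. = FALSE)
  }
  re
}

#' Design a digital Butterworth filter
#'
#' Analog Butterworth prototype mapped to the z-domain with the bilinear
#' transform (cutoff prewarped), returned as transfer-function coefficients.
#'
#' @param order Filter order (>= 1).
#' @param cutoff_hz Cutoff frequency in Hz (-3 dB point for a single pass).
#' @param fs Sampling rate in Hz.
#' @param type `"low"` or `"high"`.
#' @return A list with numerator `b` and denominator `a` (a[1] = 1).
#' @export
butter_design <- function(order, cutoff_hz, fs, type = c("low", "high")) {
  type <- match.arg(type)
  if (order < 1) stop("filter order must be >= 1", call. = FALSE)
  if (cutoff_hz <= 0 || cutoff_hz >= fs / 2) {
    stop(sprintf("cutoff %.3g Hz must lie in (0, fs/2 = %.3g Hz)",
                 cutoff_hz, fs / 2), call. = FALSE)
  }
  fs2 <- 2 * fs
  warped <- fs2 * tan(pi * cutoff_hz / fs)
  k <- seq_len(order)
  # left-half-plane prototype poles on the unit circle
  p <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  if (type == "low") {
    p <- warped * p
    z <- complex(0)
    gain <- warped^order
  } else {
    p <- warped / p
    z <- rep(0 + 0i, order)
    gain <- 1
  }
  # bilinear transform of poles/zeros; remaining zeros map to z = -1
  gain <- gain * Re(prod(fs2 - z) / prod(fs2 - p))
  pd <- (fs2 + p) / (fs2 - p)
  zd <- c((fs2 + z) / (fs2 - z), rep(-1 + 0i, order - length(z)))
  b <- gain * poly_from_roots(zd)
  a <- poly_from_roots(pd)
  list(b = b, a = a)
}

# steady-state initial conditions for a step input of height 1
# (direct form II transposed), after Gustafsson's method as commonly used
# for zero-phase filtering
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  a <- c(a, numeric(n - length(a))) / a[1]
  b <- c(b, numeric(n - length(b))) / a[1]
  if (n == 1) return(numeric(0))
  comp <- matrix(0, n - 1, n - 1)
  comp[1, ] <- -a[2:n]
  if (n > 2) comp[cbind(2:(n - 1), 1:(n - 2))] <- 1
  rhs <- b[2:n] - a[2:n] * b[1]
  solve(diag(n - 1) - t(comp), rhs)
}

# direct form II transposed IIR filter with initial state zi
lfilter <- function(b, a, x, zi = NULL) {
  n <- max(length(a), length(b))
  a <- c(a, numeric(n - length(a)))
  b <- c(b, numeric(n - length(b)))
  b <- b / a[1]; a <- a / a[1]
  nz <- n - 1
  z <- if (is.null(zi)) numeric(nz) else as.numeric(zi)
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    xi <- x[i]
    yi <- b[1] * xi + z[1]
    if (nz > 1) {
      z[1:(nz - 1)] <- b[2:nz] * xi + z[2:nz] - a[2:nz] * yi
    }
    z[nz] <- b[n] * xi - a[n] * yi
    y[i] <- yi
  }
  y
}

#' Zero-phase (forward-backward) filtering
#'
#' Applies the filter forward and backward so the result has no phase lag;
#' transients are suppressed by odd-reflection padding and matched initial
#' conditions. The effective magnitude response is the squared single-pass
#' response.
#'
#' @param b,a Transfer-function coefficients from [butter_design()].
#' @param x Numeric signal.
#' @param padlen Reflection pad length; default `3 * max(length(a), length(b))`.
#' @return Filtered signal, same length as `x`.
#' @export
filtfilt <- function(b, a, x, padlen = NULL) {
  n <- length(x)
  if (is.null(padlen)) padlen <- 3 * max(length(a), length(b))
  if (n <= padlen) {
    stop(sprintf("signal too short to filter: %d samples <= pad length %d",
                 n, padlen), call. = FALSE)
  }
  ext <- c(2 * x[1] - x[(padlen + 1):2], x, 2 * x[n] - x[(n - 1):(n - padlen)])
  zi <- lfilter_zi(b, a)
  y <- lfilter(b, a, ext, zi * ext[1])
  y <- rev(y)
  y <- lfilter(b, a, y, zi * y[1])
  y <- rev(y)
  y[(padlen + 1):(padlen + n)]
}

#' Analytic Butterworth magnitude response
#'
#' Magnitude of the digital filter designed by [butter_design()] at
#' frequency `f_hz`, computed from the closed-form analog response at the
#' bilinear-prewarped frequency. Used as an independent oracle for the
#' time-domain implementation.
#'
#' @param order,cutoff_hz,fs,type As in [butter_design()].
#' @param f_hz Frequencies (Hz) at which to evaluate.
#' @param zero_phase If `TRUE`, return the squared (forward-backward)
#'   magnitude.
#' @return Magnitude response values in `[0, 1]`.
#' @export
butter_gain <- function(order, cutoff_hz, fs, f_hz, type = c("low", "high"),
                        zero_phase = FALSE) {
  type <- match.arg(type)
  wc <- tan(pi * cutoff_hz / fs)
  w <- tan(pi * f_hz / fs)
  u <- if (type == "low") w / wc else wc / w
  g <- 1 / sqrt(1 + u^(2 * order))
  if (zero_phase) g^2 else g
}
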