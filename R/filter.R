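# Zero-phase Butterworth lowpass filtering.
#
# No DSP package is assumed: coefficients come from the standard analog
# Butterworth prototype mapped through the bilinear transform with
# frequency prewarping, and zero-phase response is obtained by filtering
# forward and backward over an odd-reflection-padded signal.

# polynomial coefficients (descending powers -> here ascending lag order)
# from a set of roots, by successive convolution; returns real part
.poly_from_roots <- function(roots) {
  coefs <- 1
  for (r in roots) coefs <- c(coefs, 0) - c(0, coefs * r)
  Re(coefs)
}

#' Digital Butterworth lowpass coefficients
#'
#' @param order Filter order.
#' @param fc Cutoff frequency (Hz, -3 dB point).
#' @param fs Sampling rate (Hz).
#' @return A list with numerator `b` and denominator `a` (both length
#'   `order + 1`, `a[1] = 1`).
#' @keywords internal
butter_lowpass <- function(order = 4L, fc, fs) {
  stopifnot(fc > 0, fc < fs / 2)
  wc <- tan(pi * fc / fs)  # prewarped analog cutoff
  k <- seq_len(order)
  poles_a <- wc * exp(1i * pi * (2 * k + order - 1) / (2 * order))
  poles_z <- (1 + poles_a) / (1 - poles_a)
  a <- .poly_from_roots(poles_z)
  b <- .poly_from_roots(rep(-1 + 0i, order))  # zeros at z = -1
  b <- b * sum(a) / sum(b)                    # unit DC gain
  list(b = b, a = a)
}

# single-pass IIR filter with zero initial conditions:
# a[1] y_t = sum_j b_j x_{t-j+1} - sum_{j>1} a_j y_{t-j+1}
.iir_filter <- function(b, a, x) {
  b <- b / a[1]
  a <- a / a[1]
  nb <- length(b)
  v <- stats::filter(c(rep(0, nb - 1), x), b, method = "convolution",
                     sides = 1)
  v <- as.numeric(v)[nb:(nb - 1 + length(x))]
  if (length(a) > 1L) {
    v <- as.numeric(stats::filter(v, -a[-1], method = "recursive"))
  }
  v
}

#' Zero-phase (forward-backward) Butterworth lowpass
#'
#' @param x Signal.
#' @param fs Sampling rate (Hz).
#' @param fc Cutoff (Hz).
#' @param order Order of the underlying one-pass filter (applied twice, so
#'   the effective attenuation is squared).
#' @return Filtered signal, same length as `x`.
#' @export
butter_filtfilt <- function(x, fs, fc, order = 4L) {
  n <- length(x)
  if (n < 10L) return(x)
  ba <- butter_lowpass(order, fc, fs)
  pad <- min(n - 1L, 300L)
  xp <- c(2 * x[1] - x[(pad + 1L):2],       # odd reflection, start
          x,
          2 * x[n] - x[(n - 1L):(n - pad)]) # odd reflection, end
  y <- .iir_filter(ba$b, ba$a, xp)
  y <- rev(.iir_filter(ba$b, ba$a, rev(y)))
  y[(pad + 1L):(pad + n)]
}

# analytic squared magnitude of the digital filter at frequency f (Hz),
# used as a test oracle: |H(f)|^2 = 1 / (1 + (tan(pi f / fs)/tan(pi fc / fs))^(2 order))
.butter_gain_sq <- function(f, fc, fs, order = 4L) {
  1 / (1 + (tan(pi * f / fs) / tan(pi * fc / fs))^(2 * order))
}
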