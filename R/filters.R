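#' Zero-phase low-pass Butterworth filter
#'
#' Applies a low-pass Butterworth filter forward and backward (two-pass),
#' cancelling the phase response: the effective magnitude response is the
#' squared magnitude `|H(f)|^2` of the single-pass design and the group delay
#' is zero. DC gain is exactly 1, so constant series pass through unchanged.
#'
#' Edge effects are controlled by extending the series at both ends with an
#' even (mirror) extension of `padlen` samples and seeding each pass with the
#' filter's steady state for the first extended sample; the extension is
#' discarded after filtering.
#'
#' @param x Numeric series.
#' @param order Butterworth order of the single-pass design (default 2).
#' @param cutoff Cutoff frequency in Hz; must be below `rate / 2`.
#' @param rate Sampling rate of `x` in Hz.
#' @param padlen Mirror-extension length in samples (default `3 * order`).
#'   `x` must be longer than `padlen`.
#' @return Filtered series, same length as `x`.
#' @export
lowpass_zero_phase <- function(x, order = 2, cutoff, rate,
                               padlen = 3 * order) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0)
    stop("cutoff must be a positive scalar (Hz)", call. = FALSE)
  if (cutoff >= rate / 2)
    stop("cutoff must be below the Nyquist frequency rate/2", call. = FALSE)
  n <- length(x)
  if (n <= padlen)
    stop(sprintf("series too short for zero-phase filtering: %d samples, need > %d",
                 n, padlen), call. = FALSE)
  bw <- signal::butter(order, cutoff / (rate / 2), type = "low")
  b <- bw$b; a <- bw$a

  # even extension excluding the edge sample
  left <- if (padlen > 0) x[(padlen + 1):2] else numeric(0)
  right <- if (padlen > 0) x[(n - 1):(n - padlen)] else numeric(0)
  ext <- c(left, x, right)

  ext <- iir_steady(b, a, ext)
  ext <- rev(iir_steady(b, a, rev(ext)))
  if (padlen > 0) ext <- ext[(padlen + 1):(padlen + n)]
  ext
}

# single IIR pass seeded with the DC steady state of the first sample, so a
# constant input is reproduced exactly
iir_steady <- function(b, a, x) {
  ord <- length(a) - 1L
  dc <- sum(b) / sum(a)
  as.numeric(signal::filter(b, a, x,
                            init.x = rep(x[1], ord),
                            init.y = rep(x[1] * dc, ord)))
}

#' Analytic squared magnitude response of the two-pass Butterworth
#'
#' The amplitude gain applied by [lowpass_zero_phase()] at frequency `f`:
#' the squared magnitude `|H(f)|^2` of the single-pass digital Butterworth
#' design (bilinear transform with frequency prewarping),
#' `(1 + (tan(pi f / rate) / tan(pi cutoff / rate))^(2 * order))^-1`.
#' Useful for checking attenuation of out-of-band components.
#'
#' @param f Frequency in Hz (vectorised); must be below `rate / 2`.
#' @inheritParams lowpass_zero_phase
#' @return Gain in `[0, 1]`.
#' @export
butterworth_two_pass_gain <- function(f, order = 2, cutoff, rate) {
  stopifnot(all(f >= 0), all(f < rate / 2), cutoff < rate / 2)
  ratio <- tan(pi * f / rate) / tan(pi * cutoff / rate)
  1 / (1 + ratio^(2 * order))
}
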