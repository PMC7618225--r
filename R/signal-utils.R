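#' Analytic signal via FFT
#'
#' Computes the analytic signal of a real series by one-sided spectrum
#' doubling, from which the instantaneous envelope (`Mod`) and phase (`Arg`)
#' are derived.
#'
#' @param x numeric vector.
#' @return complex vector of the same length.
#' @keywords internal
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 2L) stop("analytic_signal: input too short")
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1
    h[n / 2L + 1L] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Zero-phase Butterworth band-pass filter
#'
#' Forward-backward (zero-phase) filtering so that event timing is unbiased.
#'
#' @param x numeric vector.
#' @param low_hz,high_hz band edges in Hz; must satisfy 0 < low < high < fs/2.
#' @param fs sampling rate in Hz.
#' @param order filter order (default 4).
#' @return filtered vector, same length as `x`.
#' @export
bandpass <- function(x, low_hz, high_hz, fs, order = 4) {
  nyq <- fs / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq)) {
    stop("bandpass: band must satisfy 0 < low < high < fs/2")
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Zero-phase Butterworth low-pass filter
#' @inheritParams bandpass
#' @param cutoff_hz cut-off frequency in Hz.
#' @export
lowpass <- function(x, cutoff_hz, fs, order = 4) {
  nyq <- fs / 2
  if (!(cutoff_hz > 0 && cutoff_hz < nyq)) stop("lowpass: cutoff outside (0, fs/2)")
  bf <- signal::butter(order, cutoff_hz / nyq, type = "low")
  as.numeric(signal::filtfilt(bf, x))
}

#' Gaussian kernel smoothing of a series
#'
#' Convolution with a normalized Gaussian kernel, edges handled by
#' renormalizing the kernel mass inside the signal (no padding artefacts).
#'
#' @param x numeric vector.
#' @param sd_samples kernel standard deviation in samples; `sd_samples <= 0`
#'   returns `x` unchanged.
#' @keywords internal
gauss_smooth <- function(x, sd_samples) {
  if (sd_samples <= 0) return(x)
  half <- max(1L, ceiling(4 * sd_samples))
  k <- stats::dnorm(seq(-half, half), sd = sd_samples)
  k <- k / sum(k)
  n <- length(x)
  padded <- c(rep(x[1L], half), x, rep(x[n], half))
  out <- stats::filter(padded, k, sides = 2)
  as.numeric(out[(half + 1L):(half + n)])
}

#' Welch power spectral density
#'
#' Hann-windowed overlapping segments, periodograms averaged.
#'
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @param window_s segment length in seconds (default 4).
#' @param overlap fractional overlap between segments (default 0.5).
#' @return list with `freq` (Hz) and `power` (mean periodogram).
#' @keywords internal
welch_psd <- function(x, fs, window_s = 4, overlap = 0.5) {
  nwin <- round(window_s * fs)
  if (length(x) < nwin) stop("welch_psd: record shorter than one window")
  step <- max(1L, round(nwin * (1 - overlap)))
  starts <- seq(1L, length(x) - nwin + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(nwin) / (nwin + 1)))  # Hann
  nfft <- nwin
  acc <- numeric(floor(nfft / 2) + 1L)
  for (s in starts) {
    seg <- x[s:(s + nwin - 1L)]
    seg <- (seg - mean(seg)) * w
    P <- Mod(stats::fft(seg))^2 / (sum(w^2) * fs)
    acc <- acc + P[seq_along(acc)]
  }
  list(freq = (seq_along(acc) - 1L) * fs / nfft, power = acc / length(starts))
}

#' Band power from a Welch spectrum
#' @keywords internal
band_power <- function(psd, low_hz, high_hz) {
  sel <- psd$freq >= low_hz & psd$freq <= high_hz
  sum(psd$power[sel])
}

#' Local maxima of a series
#'
#' Strictly-greater-than-neighbours definition; plateaus contribute their
#' first sample.
#' @keywords internal
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

#' Unwrap phase angles
#' @keywords internal
unwrap_phase <- function(p) {
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(p[1L], d))
}
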