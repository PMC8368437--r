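# Zero-phase band filtering.
#
# The band-pass is applied in the frequency domain using the squared
# magnitude response of a 4th-order analog Butterworth band-pass prototype.
# The squared response is exactly the amplitude response of forward-backward
# (zero-phase) filtering with that Butterworth filter, but the FFT route is
# numerically robust for narrow low-frequency bands at high sampling rates,
# where the equivalent order-8 IIR polynomial is ill-conditioned in double
# precision. Odd-reflection padding suppresses edge transients.

# Power response |H(f)|^2 of an analog Butterworth band-pass of order n.
butter_bandpass_pow <- function(f, lo, hi, order = 4L) {
  x <- rep(Inf, length(f))
  pos <- f > 0
  x[pos] <- (f[pos]^2 - lo * hi) / (f[pos] * (hi - lo))
  1 / (1 + x^(2L * order))
}

# Power response of an analog Butterworth band-stop (notch) of order n.
butter_bandstop_pow <- function(f, lo, hi, order = 2L) {
  f0sq <- lo * hi
  num <- f * (hi - lo)
  den <- f^2 - f0sq
  x <- ifelse(den == 0, Inf, num / den)
  1 / (1 + x^(2L * order))
}

# Apply a real symmetric amplitude gain G(|f|) to each channel of a
# channels x samples matrix, zero-phase, with odd-reflection padding.
apply_fft_gain <- function(data, rate_hz, gain_fun, pad = NULL) {
  n <- ncol(data)
  if (n < 2L) return(data)
  npad <- pad %||% min(n - 1L, max(16L, as.integer(round(rate_hz))))
  # grow the padding so the FFT length is a fast 2-3-5 composite
  target <- stats::nextn(n + 2L * npad, c(2L, 3L, 5L))
  npad_r <- npad + (target - n - 2L * npad)
  if (npad_r > n - 1L) { npad_r <- npad }       # keep reflection well defined
  x <- t(data)                                   # samples x channels
  if (npad > 0L) {
    first <- x[1L, , drop = FALSE]
    last <- x[n, , drop = FALSE]
    left <- 2 * first[rep(1L, npad), , drop = FALSE] - x[(npad + 1L):2L, , drop = FALSE]
    right <- 2 * last[rep(1L, npad_r), , drop = FALSE] - x[(n - 1L):(n - npad_r), , drop = FALSE]
    x <- rbind(left, x, right)
  }
  m <- nrow(x)
  freqs <- c(seq_len(m) - 1L)
  freqs[freqs > m / 2] <- freqs[freqs > m / 2] - m
  f_hz <- abs(freqs) * rate_hz / m
  g <- gain_fun(f_hz)
  y <- Re(stats::mvfft(stats::mvfft(x) * g, inverse = TRUE)) / m
  t(y[(npad + 1L):(npad + n), , drop = FALSE])
}

#' Zero-phase band-pass filtering of a recording
#'
#' Filters every channel with a zero-phase band-pass whose amplitude
#' response is the squared magnitude of a 4th-order Butterworth band-pass
#' (the response of forward-backward filtering). When the band contains
#' 50 Hz, a zero-phase 2nd-order Butterworth band-stop at 48-52 Hz is
#' applied in the same pass so that power-line content never enters the
#' analysis.
#'
#' @param rec A [meg_recording()] (or plain channels x samples matrix with
#'   `rate_hz` supplied via `rate_hz`).
#' @param band A [band_definition()], a `c(lo, hi)` pair in Hz, or a row of
#'   [canonical_bands()].
#' @param notch_50 Apply the 50 Hz notch when the band spans it (default
#'   TRUE).
#' @param rate_hz Sampling rate, only needed when `rec` is a bare matrix.
#' @return Object of the same kind as `rec` with filtered data.
#' @examples
#' rec <- meg_recording(matrix(sin(2 * pi * 10 * (0:999) / 500), 1), 500)
#' out <- bandpass(rec, c(8, 12))   # ~unit gain at 10 Hz
#' @export
bandpass <- function(rec, band, notch_50 = TRUE, rate_hz = NULL) {
  band <- as_band(band)
  is_rec <- inherits(rec, "meg_recording")
  data <- if (is_rec) rec$data else as.matrix(rec)
  rate <- if (is_rec) rec$rate_hz else rate_hz
  if (is.null(rate)) stop_config("rate_hz required when filtering a bare matrix")
  if (band$hi_hz >= rate / 2)
    stop_config("band upper edge %g Hz is not below the Nyquist frequency %g Hz",
                band$hi_hz, rate / 2)
  has_50 <- notch_50 && band$lo_hz < 50 && band$hi_hz > 50
  gain <- function(f) {
    g <- butter_bandpass_pow(f, band$lo_hz, band$hi_hz, order = 4L)
    if (has_50) g <- g * butter_bandstop_pow(f, 48, 52, order = 2L)
    g
  }
  pad <- min(ncol(data) - 1L, max(16L, as.integer(round(2 * rate / band$lo_hz))))
  out <- apply_fft_gain(data, rate, gain, pad = pad)
  if (is_rec) meg_recording(out, rate, rec$channel_ids, rec$t0, rec$units) else out
}

# 1/f ("pink", exponent 1) Gaussian noise, one column per channel,
# scaled to standard deviation `sd` per channel. Uses the current RNG.
pink_noise <- function(n, n_channels, sd = 1) {
  if (sd == 0 || n == 0L) return(matrix(0, n, n_channels))
  white <- matrix(rnorm(n * n_channels), n, n_channels)
  freqs <- c(seq_len(n) - 1L)
  freqs[freqs > n / 2] <- freqs[freqs > n / 2] - n
  shape <- ifelse(freqs == 0, 0, 1 / sqrt(abs(freqs)))
  y <- Re(stats::mvfft(stats::mvfft(white) * shape, inverse = TRUE)) / n
  sds <- apply(y, 2L, sd)
  sds[sds == 0] <- 1
  sweep(y, 2L, sds / sd, "/")
}
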