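# Gammatone filterbank on the ERB-rate scale (Glasberg & Moore) and the
# auditory spectrogram built from it. Filters are FIR truncations of the
# 4th-order gammatone impulse response, applied by FFT convolution.

erb_bandwidth <- function(f_hz) 24.7 * (4.37 * f_hz / 1000 + 1)

hz_to_erb_rate <- function(f_hz) 21.4 * log10(4.37 * f_hz / 1000 + 1)

erb_rate_to_hz <- function(e) (10^(e / 21.4) - 1) * 1000 / 4.37

#' ERB-spaced center frequencies
#'
#' @param n_channels Number of channels.
#' @param fmin_hz,fmax_hz Frequency range in Hz.
#' @return Strictly increasing vector of center frequencies (Hz).
#' @export
erb_space <- function(n_channels, fmin_hz, fmax_hz) {
  stopifnot(n_channels >= 1, fmin_hz > 0, fmax_hz > fmin_hz)
  erb_rate_to_hz(seq(hz_to_erb_rate(fmin_hz), hz_to_erb_rate(fmax_hz),
                     length.out = n_channels))
}

# FIR kernel of a 4th-order gammatone, unit peak frequency response
gammatone_kernel <- function(cf_hz, sample_rate, order = 4L, dur_s = 0.05) {
  b <- 1.019 * erb_bandwidth(cf_hz)
  n <- max(32L, round(dur_s * sample_rate))
  t <- (seq_len(n) - 1) / sample_rate
  k <- t^(order - 1) * exp(-2 * pi * b * t) * cos(2 * pi * cf_hz * t)
  # normalize so a tone at cf passes at unit gain
  resp <- sum(k * exp(-2i * pi * cf_hz * t))
  k / Mod(resp)
}

# linear convolution via FFT, returning the "same" central part so that the
# output is aligned with the input (kernel treated as causal; delay kept)
fft_conv <- function(x, k) {
  n <- length(x) + length(k) - 1L
  nfft <- 2^ceiling(log2(n))
  y <- Re(stats::fft(stats::fft(c(x, numeric(nfft - length(x)))) *
                     stats::fft(c(k, numeric(nfft - length(k)))), inverse = TRUE)) / nfft
  y[seq_along(x)]
}

# zero-phase band filtering: forward then time-reversed pass, as used by the
# scrambling procedure (squares the magnitude response, cancels phase)
gammatone_band_zerophase <- function(x, cf_hz, sample_rate) {
  k <- gammatone_kernel(cf_hz, sample_rate)
  rev(fft_conv(rev(fft_conv(x, k)), k))
}

#' Gammatone auditory spectrogram
#'
#' Decomposes a mono waveform with an ERB-spaced gammatone filterbank (a
#' linear approximation of cochlear frequency resolution), half-wave
#' rectifies each band and frames the rectified signal into a smoothed
#' envelope matrix.
#'
#' @param wave Numeric mono waveform.
#' @param sample_rate Sampling rate (Hz).
#' @param n_channels Number of gammatone channels.
#' @param fmin_hz Lowest center frequency (Hz).
#' @param fmax_hz Highest center frequency (Hz); defaults to 90% of Nyquist.
#' @param frame_ms,hop_ms Analysis frame length and hop (ms).
#' @return Object of class `auditory_spectrogram`: list with `envelope`
#'   (channel x frame, nonnegative), `center_freqs` (Hz, increasing) and
#'   `frame_times` (s).
#' @export
gammatone_spectrogram <- function(wave, sample_rate, n_channels = 64L,
                                  fmin_hz = 80, fmax_hz = NULL,
                                  frame_ms = 10, hop_ms = 5) {
  stopifnot(is.numeric(wave), all(is.finite(wave)))
  nyq <- sample_rate / 2
  if (is.null(fmax_hz)) fmax_hz <- 0.9 * nyq
  if (fmax_hz > nyq) stop("fmax_hz (", fmax_hz, ") exceeds the Nyquist frequency (", nyq, ")")
  cfs <- erb_space(n_channels, fmin_hz, fmax_hz)
  frame_len <- max(1L, round(frame_ms / 1000 * sample_rate))
  hop <- max(1L, round(hop_ms / 1000 * sample_rate))
  starts <- seq(1L, max(1L, length(wave) - frame_len + 1L), by = hop)
  env <- matrix(0, nrow = n_channels, ncol = length(starts))
  for (ch in seq_len(n_channels)) {
    band <- fft_conv(wave, gammatone_kernel(cfs[ch], sample_rate))
    rect <- pmax(band, 0)
    cs <- c(0, cumsum(rect))
    env[ch, ] <- (cs[pmin(starts + frame_len, length(wave) + 1L)] - cs[starts]) / frame_len
  }
  structure(list(envelope = env, center_freqs = cfs,
                 frame_times = (starts - 1 + frame_len / 2) / sample_rate,
                 hop_s = hop / sample_rate),
            class = "auditory_spectrogram")
}
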