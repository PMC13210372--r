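# Log-power mel spectrogram for 16 kHz cry audio.

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# Triangular mel filterbank, n_mels x (n_fft/2 + 1).
mel_filterbank <- function(n_mels = 128L, n_fft = 2048L, sr = 16000L,
                           fmin = 0, fmax = sr / 2) {
  n_bins <- n_fft %/% 2L + 1L
  freqs <- seq(0, sr / 2, length.out = n_bins)
  mel_pts <- seq(hz_to_mel(fmin), hz_to_mel(fmax), length.out = n_mels + 2L)
  hz_pts <- mel_to_hz(mel_pts)
  fb <- matrix(0, n_mels, n_bins)
  for (m in seq_len(n_mels)) {
    lo <- hz_pts[m]; ctr <- hz_pts[m + 1]; hi <- hz_pts[m + 2]
    up <- (freqs - lo) / (ctr - lo)
    down <- (hi - freqs) / (hi - ctr)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  attr(fb, "center_hz") <- hz_pts[2:(n_mels + 1L)]
  fb
}

#' Log-power mel spectrogram
#'
#' 2048-point FFT frames with hop 1024 (50% overlap), Hann window, 128 mel
#' bands. No center padding, so the frame count is exactly
#' `1 + floor((n - 2048) / 1024)`. Power is floored at 1e-10 before the log.
#'
#' @param waveform mono samples at `sr` Hz
#' @param sr sampling rate (Hz)
#' @param n_mels number of mel bands
#' @param n_fft FFT size
#' @param hop hop length in samples
#' @return `n_mels x n_frames` matrix of log-power values; attribute
#'   `center_hz` gives each band's center frequency
#' @export
mel_spectrogram <- function(waveform, sr = 16000L, n_mels = 128L,
                            n_fft = 2048L, hop = n_fft %/% 2L) {
  n <- length(waveform)
  if (n < n_fft)
    np_stop("np_insufficient_data_error",
            "waveform has %d samples; at least %d required", n, n_fft)
  n_frames <- 1L + (n - n_fft) %/% hop
  win <- 0.5 - 0.5 * cos(2 * pi * seq(0, n_fft - 1) / n_fft) # Hann
  starts <- (seq_len(n_frames) - 1L) * hop
  frames <- vapply(starts, function(s) waveform[(s + 1):(s + n_fft)] * win,
                   numeric(n_fft))
  spec <- stats::mvfft(frames)
  power <- Mod(spec[seq_len(n_fft %/% 2L + 1L), , drop = FALSE])^2
  fb <- mel_filterbank(n_mels, n_fft, sr)
  out <- log(pmax(fb %*% power, 1e-10))
  dimnames(out) <- NULL
  attr(out, "center_hz") <- attr(fb, "center_hz")
  out
}
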