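# Acoustic features for the vocal concepts: framewise RMS, voiced runs,
# autocorrelation F0, harmonic-to-noise ratio, spectral flux, inter-cry pauses.

VOICING_FLOOR <- 0.05   # RMS floor separating vocalization from background
F0_MIN <- 200
F0_MAX <- 1000

frame_rms <- function(x, frame) {
  n_frames <- length(x) %/% frame
  if (n_frames == 0) return(numeric(0))
  m <- matrix(x[seq_len(n_frames * frame)], nrow = frame)
  sqrt(colMeans(m^2))
}

# Maximal runs of TRUE; returns data.frame(start, end, len) in frame indices.
runs_of <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep], len = r$lengths[keep])
}

#' Acoustic feature summary of a cry waveform
#'
#' Works on 25-ms analysis frames (with 50-ms frames for the cry-intensity RMS
#' criterion). Voicing is an RMS floor of 0.05; F0 comes from the normalized
#' autocorrelation peak in 200-1000 Hz with parabolic refinement; the
#' harmonic-to-noise ratio is `r / (1 - r)` for the autocorrelation peak `r`;
#' spectral irregularity is the mean normalized frame-to-frame spectral flux
#' over voiced frames; pauses are unvoiced stretches flanked by voiced runs.
#'
#' @param wave mono waveform at `sr` Hz, at least 1 s
#' @param sr sampling rate (Hz)
#' @return list of summary features used by [detect_vocal_concepts()]
#' @export
vocal_features <- function(wave, sr = 16000L) {
  if (length(wave) < sr)
    np_stop("np_insufficient_data_error",
            "need at least 1 s of audio, got %.2f s", length(wave) / sr)
  f25 <- as.integer(sr * 0.025)
  f50 <- as.integer(sr * 0.050)
  rms25 <- frame_rms(wave, f25)
  rms50 <- frame_rms(wave, f50)
  voiced <- rms25 > VOICING_FLOOR
  vr <- runs_of(voiced)

  # C5: longest voiced run and the max over >=500 ms runs of mean 50-ms RMS.
  sustained_rms <- 0
  max_run_s <- 0
  if (nrow(vr) > 0) {
    max_run_s <- max(vr$len) * 0.025
    long <- vr[vr$len * 0.025 > 0.5, , drop = FALSE]
    if (nrow(long) > 0) {
      sustained_rms <- max(vapply(seq_len(nrow(long)), function(i) {
        t0 <- (long$start[i] - 1) * 0.025
        t1 <- long$end[i] * 0.025
        i50 <- which((seq_along(rms50) - 1) * 0.05 >= t0 &
                     seq_along(rms50) * 0.05 <= t1 + 0.05)
        if (length(i50) == 0) 0 else max(mean(rms50[i50]), 0)
      }, numeric(1)))
    }
  }

  # C8: pauses strictly between voiced runs (within a cry episode).
  max_pause_s <- 0
  if (nrow(vr) >= 2) {
    gaps <- (vr$start[-1] - vr$end[-nrow(vr)] - 1L) * 0.025
    max_pause_s <- max(gaps)
  }

  # F0 / HNR / flux on voiced 25-ms frames via FFT autocorrelation.
  f0_frames <- numeric(0)
  hnr_frames <- numeric(0)
  flux_frames <- numeric(0)
  vidx <- which(voiced)
  if (length(vidx) > 0) {
    # Subsample voiced frames for pitch analysis; ~40 anchor frames plus
    # their immediate successors (for spectral flux) suffice for stable
    # medians over a 10-s clip.
    anchors <- vidx[unique(round(seq(1, length(vidx),
                                     length.out = min(40, length(vidx)))))]
    pidx <- sort(unique(c(anchors, intersect(anchors + 1L, vidx))))
    nfft <- 2^ceiling(log2(2L * f25))
    fm <- matrix(0, nfft, length(pidx))
    for (j in seq_along(pidx)) {
      i0 <- (pidx[j] - 1L) * f25
      fm[seq_len(f25), j] <- wave[(i0 + 1):(i0 + f25)]
    }
    sp <- stats::mvfft(fm)
    mag <- Mod(sp)
    ac <- Re(stats::mvfft(mag^2, inverse = TRUE)) / nfft
    lag_lo <- max(2L, floor(sr / F0_MAX))
    lag_hi <- min(f25 - 2L, ceiling(sr / F0_MIN))
    lags <- lag_lo:lag_hi
    unbias <- f25 / (f25 - lags)       # correct the biased estimator
    f0_frames <- numeric(length(pidx))
    hnr_frames <- numeric(length(pidx))
    for (j in seq_along(pidx)) {
      r <- clamp(ac[lags + 1L, j] * unbias / ac[1L, j], -1, 1)
      # Octave-error guard: take the SMALLEST lag whose peak is within 10%
      # of the global maximum (subharmonic lags score equally high on a
      # purely harmonic source).
      top <- max(r)
      cand <- which(r >= 0.9 * top)
      pk <- cand[1]
      # local maximum refinement around the chosen candidate
      while (pk < length(r) && r[pk + 1] > r[pk]) pk <- pk + 1L
      lag_star <- lags[pk]
      if (pk > 1 && pk < length(r)) {
        y1 <- r[pk - 1]; y2 <- r[pk]; y3 <- r[pk + 1]
        den <- y1 - 2 * y2 + y3
        if (abs(den) > 1e-12) lag_star <- lags[pk] + 0.5 * (y1 - y3) / den
      }
      f0_frames[j] <- sr / lag_star
      rpk <- clamp(r[pk], 0, 0.999)
      hnr_frames[j] <- rpk / (1 - rpk)
    }
    # Spectral flux between consecutive analysed voiced frames.
    half <- seq_len(nfft %/% 2L + 1L)
    consec <- which(diff(pidx) == 1L)
    if (length(consec) > 0) {
      # Flux of standardized spectra: 1 - cor(a, b) equals half the squared
      # Euclidean flux between z-scored spectra, so a stationary harmonic
      # source scores ~0 and decorrelated (noise-dominated) frames score ~1.
      flux_frames <- vapply(consec, function(j) {
        a <- mag[half, j]; b <- mag[half, j + 1L]
        if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) return(0)
        clamp(1 - stats::cor(a, b), 0, 1)
      }, numeric(1))
    }
  }

  list(
    sustained_rms = sustained_rms,
    max_run_s = max_run_s,
    max_pause_s = max_pause_s,
    n_voiced_runs = nrow(vr),
    f0_hz = if (length(f0_frames)) stats::median(f0_frames) else NA_real_,
    hnr = if (length(hnr_frames)) stats::median(hnr_frames) else NA_real_,
    irregularity = if (length(flux_frames)) mean(flux_frames) else NA_real_,
    voiced_fraction = mean(voiced)
  )
}
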