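# Symlet-4 discrete wavelet transform (periodized) and soft-threshold denoising.
# Used by the physiological preprocessing stage; no wavelet package is assumed.

sym4_dec_lo <- c(-0.07576571478927333, -0.02963552764599851, 0.49761866763201545,
                 0.80373875180591614, 0.29785779560527736, -0.09921954357684722,
                 -0.01260396726203783, 0.03222310060404270)

sym4_filters <- function() {
  lo <- sym4_dec_lo
  n <- length(lo)
  # Quadrature mirror relations.
  hi <- rev(lo) * (-1)^(seq_len(n))
  list(dec_lo = lo, dec_hi = hi, rec_lo = rev(lo), rec_hi = rev(hi))
}

# Circular (periodized) convolution + downsample by 2. Signal length must be even.
dwt_step <- function(x, filt) {
  n <- length(x)
  L <- length(filt$dec_lo)
  idx <- outer(seq(2, n, by = 2), 0:(L - 1), function(k, m) ((k - 1 - m) %% n) + 1)
  xm <- matrix(x[idx], nrow = n / 2)
  list(approx = as.numeric(xm %*% filt$dec_lo),
       detail = as.numeric(xm %*% filt$dec_hi))
}

# Exact adjoint of dwt_step: for an orthogonal wavelet the periodized
# synthesis operator is the transpose of the analysis operator.
idwt_step <- function(approx, detail, filt) {
  n2 <- length(approx) * 2L
  x <- numeric(n2)
  L <- length(filt$dec_lo)
  ks <- seq(2, n2, by = 2)
  for (m in 0:(L - 1)) {
    pos <- ((ks - 1L - m) %% n2) + 1L
    contrib <- filt$dec_lo[m + 1] * approx + filt$dec_hi[m + 1] * detail
    x[pos] <- x[pos] + contrib
  }
  x
}

#' Multi-level periodized Symlet-4 decomposition
#'
#' @param x numeric signal; length must be a multiple of `2^level`
#' @param level decomposition depth
#' @return list with `approx` and a list `details` (finest first)
#' @export
sym4_dwt <- function(x, level = 5L) {
  if (length(x) %% (2^level) != 0)
    np_stop("np_shape_error", "signal length %d is not a multiple of 2^%d",
            length(x), level)
  filt <- sym4_filters()
  details <- vector("list", level)
  cur <- x
  for (l in seq_len(level)) {
    s <- dwt_step(cur, filt)
    details[[l]] <- s$detail
    cur <- s$approx
  }
  list(approx = cur, details = details, level = level)
}

#' Inverse of [sym4_dwt()]
#' @param decomp decomposition from [sym4_dwt()]
#' @return reconstructed signal
#' @export
sym4_idwt <- function(decomp) {
  filt <- sym4_filters()
  cur <- decomp$approx
  for (l in rev(seq_len(decomp$level))) {
    cur <- idwt_step(cur, decomp$details[[l]], filt)
  }
  cur
}

#' Wavelet denoising (Symlet-4, level 5, soft universal threshold)
#'
#' Noise scale is estimated from the median absolute deviation of the finest
#' detail band (`MAD / 0.6745`); all detail bands are soft-thresholded at
#' `sigma * sqrt(2 * log(n))`. Signals shorter than `2^level` samples are
#' returned unchanged (nothing to decompose). A clean signal with negligible
#' fine-scale energy passes through essentially unaltered, which makes the
#' operation idempotent on already-denoised input.
#'
#' @param x numeric signal (no NA)
#' @param level decomposition depth (default 5)
#' @return denoised signal of the same length
#' @export
wavelet_denoise <- function(x, level = 5L) {
  n0 <- length(x)
  block <- 2^level
  if (n0 < block) return(x)
  # Pad by edge replication to a multiple of 2^level, truncate afterwards.
  n <- ceiling(n0 / block) * block
  xp <- c(x, rep(x[n0], n - n0))
  d <- sym4_dwt(xp, level)
  sigma <- stats::median(abs(d$details[[1]])) / 0.6745
  if (sigma > 0) {
    thr <- sigma * sqrt(2 * log(n))
    d$details <- lapply(d$details, function(w) sign(w) * pmax(abs(w) - thr, 0))
  }
  sym4_idwt(d)[seq_len(n0)]
}
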