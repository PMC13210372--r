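# Lightweight modality encoders: dilated temporal convolutions producing
# 128-dim embeddings. The physio and mel-spectrogram streams use a 3-layer
# TCN (kernel 3, dilations 1/2/4); the facial stream uses a 2-layer temporal
# conv. Absent modalities yield exact zero vectors without evaluating the
# encoder. At desk scale the encoders serve as fixed random feature maps;
# the canonical concept path is the rule-based detectors.

conv1d_causal <- function(X, W, b, dilation = 1L) {
  # X: T x Cin; W: k x Cin x Cout; causal zero padding.
  Tn <- nrow(X)
  k <- dim(W)[1]
  Cout <- dim(W)[3]
  Z <- matrix(b, Tn, Cout, byrow = TRUE)
  for (j in seq_len(k)) {
    shift <- (j - 1L) * dilation
    if (shift >= Tn) next
    rows <- seq_len(Tn - shift)
    Z[rows + shift, ] <- Z[rows + shift, ] + X[rows, , drop = FALSE] %*% W[j, , ]
  }
  Z
}

tcn_forward <- function(X, layers) {
  for (ly in layers) {
    X <- pmax(conv1d_causal(X, ly$W, ly$b, ly$dilation), 0)
  }
  colMeans(X)   # global average pool over time
}

init_tcn <- function(c_in, hidden, n_layers, dilations, k = 3L) {
  layers <- vector("list", n_layers)
  cin <- c_in
  for (l in seq_len(n_layers)) {
    layers[[l]] <- list(
      W = array(stats::rnorm(k * cin * hidden, 0, sqrt(2 / (k * cin))),
                dim = c(k, cin, hidden)),
      b = numeric(hidden), dilation = dilations[l]
    )
    cin <- hidden
  }
  layers
}

#' Initialize the three modality encoders
#'
#' @param seed RNG seed
#' @param hidden hidden dimension (128)
#' @return list with `video`, `audio`, `physio` TCN stacks
#' @export
init_encoder_params <- function(seed = 42L, hidden = HID) {
  with_seed(seed, list(
    video = init_tcn(4L, hidden, 2L, c(1L, 2L)),
    audio = init_tcn(128L, hidden, 3L, c(1L, 2L, 4L)),
    physio = init_tcn(4L, hidden, 3L, c(1L, 2L, 4L))
  ))
}

# Reference normalization statistics for the physiological channels.
PHYSIO_NORM <- list(mean = c(hr = 140, spo2 = 96, rr = 45, map = 45),
                    sd = c(hr = 15, spo2 = 2, rr = 8, map = 8))

#' Encode a clip's modalities to 128-dim embeddings
#'
#' @param clip a 10-second [episode()]
#' @param enc_params from [init_encoder_params()]
#' @return list `h_v`, `h_a`, `h_p`; absent modalities are exact zero vectors
#' @export
encode_modalities <- function(clip, enc_params = init_encoder_params()) {
  stopifnot(inherits(clip, "np_episode"))
  zero <- numeric(HID)
  h_v <- if (!is.null(clip$facial)) {
    X <- as.matrix(clip$facial[, paste0("c", 1:4)])
    tcn_forward(X, enc_params$video)
  } else zero
  h_a <- if (!is.null(clip$audio)) {
    mel <- mel_spectrogram(clip$audio)
    mel <- (mel - mean(mel)) / max(stats::sd(mel), 1e-8)
    tcn_forward(t(mel), enc_params$audio)
  } else zero
  h_p <- if (!is.null(clip$physio)) {
    ph <- clip$physio[clip$physio$time >= -1e-6 &
                      clip$physio$time < clip$duration_s - 1e-6, , drop = FALSE]
    X <- matrix(0, nrow(ph), 4)
    for (i in seq_along(PHYSIO_NORM$mean)) {
      nm <- names(PHYSIO_NORM$mean)[i]
      if (nm %in% names(ph) && !all(is.na(ph[[nm]]))) {
        v <- ph[[nm]]
        v[is.na(v)] <- PHYSIO_NORM$mean[i]
        X[, i] <- (v - PHYSIO_NORM$mean[i]) / PHYSIO_NORM$sd[i]
      }
    }
    tcn_forward(X, enc_params$physio)
  } else zero
  list(h_v = h_v, h_a = h_a, h_p = h_p)
}
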