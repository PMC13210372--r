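# Rule-based concept detection (12 clinical concepts) and learned concept
# heads. Firing is the strict binary clinical rule; a graded activation in
# [0,1] (logistic of the normalized threshold margin) feeds the fusion graph.

#' Construct a concept vector
#'
#' @param activations 12 values in \[0,1\], ordered C1..C12
#' @param available 12 logicals; an unavailable concept is never fired
#' @param fired 12 logicals: strict rule firing (forced FALSE when unavailable)
#' @param provenance character vector, "rule" or "learned", per concept
#' @return object of class `np_concept_vector`
#' @export
concept_vector <- function(activations, available, fired,
                           provenance = rep("rule", 12)) {
  stopifnot(length(activations) == 12, length(available) == 12,
            length(fired) == 12)
  if (any(activations < -1e-9 | activations > 1 + 1e-9, na.rm = TRUE))
    np_stop("np_validation_error", "activations must lie in [0,1]")
  activations[!available] <- 0
  fired <- fired & available
  structure(list(
    activations = stats::setNames(clamp(as.numeric(activations), 0, 1),
                                  concept_ids()),
    available = stats::setNames(as.logical(available), concept_ids()),
    fired = stats::setNames(as.logical(fired), concept_ids()),
    provenance = stats::setNames(provenance, concept_ids())
  ), class = "np_concept_vector")
}

#' @export
print.np_concept_vector <- function(x, ...) {
  cat("<np_concept_vector>\n")
  print(round(x$activations, 3))
  cat("fired:", paste(names(x$fired)[x$fired], collapse = " "), "\n")
  invisible(x)
}

#' Facial concepts C1-C4 from facial action channels
#'
#' Activation per concept is the 90th-percentile channel value over the clip;
#' a concept fires when its activation is strictly above the GA-resolved
#' stratified threshold.
#'
#' @param facial data.frame with channels `c1..c4` (30 fps), or NULL
#' @param ga_weeks gestational age for threshold resolution
#' @param thresholds resolved thresholds from [resolve_thresholds()]
#' @return list: `activation`, `fired`, `available` (length 4 each)
#' @export
detect_facial_concepts <- function(facial, ga_weeks,
                                   thresholds = resolve_thresholds(ga_weeks = ga_weeks)) {
  if (is.null(facial)) {
    return(list(activation = rep(0, 4), fired = rep(FALSE, 4),
                available = rep(FALSE, 4)))
  }
  act <- vapply(paste0("c", 1:4), function(ch)
    unname(stats::quantile(facial[[ch]], 0.9, na.rm = TRUE)), numeric(1))
  thr <- vapply(paste0("C", 1:4), function(k) thresholds[[k]]$activation,
                numeric(1))
  list(activation = clamp(unname(act), 0, 1), fired = unname(act > thr),
       available = rep(TRUE, 4))
}

#' Vocal concepts C5-C8 from the cry waveform
#'
#' C5 fires on a vocalization sustained over 500 ms with RMS energy above 0.3;
#' C6 on median F0 above the GA-resolved limit (450 Hz preterm, 500 Hz term);
#' C7 on harmonic-to-noise ratio below 0.5 together with spectral irregularity
#' above 0.3; C8 on an inter-vocalization pause above 200 ms within a cry
#' episode. All comparisons are strict.
#'
#' @param waveform mono 16 kHz samples, or NULL (marks C5-C8 unavailable)
#' @param ga_weeks gestational age
#' @param thresholds resolved thresholds
#' @param sr sampling rate
#' @return list: `activation`, `fired`, `available` (length 4), plus the raw
#'   `features`
#' @export
detect_vocal_concepts <- function(waveform, ga_weeks,
                                  thresholds = resolve_thresholds(ga_weeks = ga_weeks),
                                  sr = 16000L) {
  if (is.null(waveform)) {
    return(list(activation = rep(0, 4), fired = rep(FALSE, 4),
                available = rep(FALSE, 4), features = NULL))
  }
  ft <- vocal_features(waveform, sr)
  thr5 <- thresholds$C5; thr6 <- thresholds$C6
  thr7 <- thresholds$C7; thr8 <- thresholds$C8

  # C5: graded by the sustained-RMS margin; zero when nothing is sustained.
  a5 <- if (ft$max_run_s > thr5$sustained_s)
    margin_activation(ft$sustained_rms, thr5$rms) else 0
  f5 <- ft$max_run_s > thr5$sustained_s && ft$sustained_rms > thr5$rms

  voiced <- ft$voiced_fraction > 0 && !is.na(ft$f0_hz)
  a6 <- if (voiced) margin_activation(ft$f0_hz, thr6$f0_hz) else 0
  f6 <- voiced && ft$f0_hz > thr6$f0_hz

  a7 <- if (voiced && !is.na(ft$irregularity)) {
    min(margin_activation(-ft$hnr, -thr7$hnr, scale = 0.1 * thr7$hnr),
        margin_activation(ft$irregularity, thr7$irregularity))
  } else 0
  f7 <- voiced && !is.na(ft$irregularity) &&
    ft$hnr < thr7$hnr && ft$irregularity > thr7$irregularity

  a8 <- if (ft$n_voiced_runs >= 2)
    margin_activation(ft$max_pause_s, thr8$pause_s) else 0
  f8 <- ft$n_voiced_runs >= 2 && ft$max_pause_s > thr8$pause_s

  list(activation = c(a5, a6, a7, a8), fired = c(f5, f6, f7, f8),
       available = rep(TRUE, 4), features = ft)
}

#' Physiological concepts C9-C12 from the 100 Hz series
#'
#' The 2-minute baseline is taken from negative-time rows (pre-clip history);
#' if absent, the first half of the available series serves as a degraded
#' baseline (with a warning when under 30 s of history is available). The
#' SpO2 "4%" criterion is read as 4 percentage points.
#'
#' @param physio data.frame with `time`, `hr`, `spo2`, `rr`, optional `map`
#' @param thresholds resolved thresholds
#' @return list: `activation`, `fired`, `available` (length 4)
#' @export
detect_physio_concepts <- function(physio,
                                   thresholds = default_thresholds()) {
  if (is.null(physio)) {
    return(list(activation = rep(0, 4), fired = rep(FALSE, 4),
                available = rep(FALSE, 4)))
  }
  t <- physio$time
  hist_idx <- which(t < 0)
  clip_idx <- which(t >= 0)
  if (length(hist_idx) == 0) {
    half <- seq_len(floor(nrow(physio) / 2))
    hist_idx <- half
    clip_idx <- setdiff(seq_len(nrow(physio)), half)
  }
  span_s <- diff(range(t[hist_idx]))
  if (span_s < 30)
    np_warn("np_degraded_baseline_warning",
            "only %.1f s of baseline history; C9/C10 baselines are degraded",
            span_s)

  thr9 <- thresholds$C9; thr10 <- thresholds$C10
  thr11 <- thresholds$C11; thr12 <- thresholds$C12

  hr_base <- mean(physio$hr[hist_idx], na.rm = TRUE)
  hr_clip <- mean(physio$hr[clip_idx], na.rm = TRUE)
  rel <- (hr_clip - hr_base) / hr_base
  f9 <- isTRUE(rel > thr9$rel_increase) || isTRUE(hr_clip > thr9$abs_bpm)
  a9 <- max(margin_activation(rel, thr9$rel_increase),
            margin_activation(hr_clip, thr9$abs_bpm))

  # C10: max drop from a running 30-s peak, plus the absolute branch.
  spo2 <- physio$spo2
  drop <- 0
  if (sum(!is.na(spo2)) > 1) {
    w <- max(2L, round(thr10$window_s * PHYSIO_RATE))
    peak <- rolling_max(spo2, w)
    drop <- max(peak - spo2, na.rm = TRUE)
  }
  min_clip <- suppressWarnings(min(spo2[clip_idx], na.rm = TRUE))
  f10 <- isTRUE(drop > thr10$drop_points) || isTRUE(min_clip < thr10$abs_pct)
  a10 <- max(margin_activation(drop, thr10$drop_points),
             margin_activation(-min_clip, -thr10$abs_pct,
                               scale = 0.1 * thr10$abs_pct))

  # C11: coefficient of variation of RR over the trailing 1-min window.
  w11 <- which(t >= max(t) - thr11$window_s)
  rr <- physio$rr[w11]
  cv <- stats::sd(rr, na.rm = TRUE) / mean(rr, na.rm = TRUE)
  f11 <- isTRUE(cv > thr11$cv)
  a11 <- margin_activation(cv, thr11$cv)

  if (!"map" %in% names(physio) || all(is.na(physio$map))) {
    f12 <- FALSE; a12 <- 0; avail12 <- FALSE
  } else {
    map_base <- mean(physio$map[hist_idx], na.rm = TRUE)
    map_clip <- mean(physio$map[clip_idx], na.rm = TRUE)
    inc <- map_clip - map_base
    f12 <- isTRUE(inc > thr12$increase_mmhg)
    a12 <- margin_activation(inc, thr12$increase_mmhg)
    avail12 <- TRUE
  }

  list(activation = clamp(c(a9, a10, a11, a12), 0, 1),
       fired = c(f9, f10, f11, f12),
       available = c(TRUE, TRUE, TRUE, avail12))
}

#' Rule-based concept extraction for a whole episode
#'
#' Runs the three modality detectors and assembles the canonical 12-concept
#' vector with availability derived from the episode's modality mask.
#'
#' @param ep an [episode()]
#' @param thresholds optional pre-resolved thresholds (resolved from the
#'   episode's GA when omitted)
#' @return an `np_concept_vector`
#' @export
detect_concepts <- function(ep, thresholds = NULL) {
  stopifnot(inherits(ep, "np_episode"))
  ga <- ep$meta$ga_weeks
  if (is.null(thresholds)) thresholds <- resolve_thresholds(ga_weeks = ga)
  fa <- detect_facial_concepts(ep$facial, ga, thresholds)
  vo <- detect_vocal_concepts(ep$audio, ga, thresholds)
  ph <- detect_physio_concepts(ep$physio, thresholds)
  concept_vector(
    activations = c(fa$activation, vo$activation, ph$activation),
    available = c(fa$available, vo$available, ph$available),
    fired = c(fa$fired, vo$fired, ph$fired)
  )
}

#' Learned concept heads (sigmoid linear projections per modality)
#'
#' Projects each 128-dim modality embedding through a 12-way sigmoid linear
#' head, giving the 3 x 12 concept matrix. The canonical 12-vector takes each
#' concept from its source modality row (C1-C4 from video, C5-C8 from audio,
#' C9-C12 from physio); concepts whose source embedding is exactly zero
#' (absent modality) are marked unavailable.
#'
#' @param h_v,h_a,h_p 128-dim embeddings (zero vector when absent)
#' @param head_params list with `W_v`, `W_a`, `W_p` (12 x 128) and
#'   `b_v`, `b_a`, `b_p` (length 12)
#' @return list: `matrix` (3 x 12, rows video/audio/physio), `canonical`
#'   (length 12), `available` (length 12)
#' @export
concept_heads_forward <- function(h_v, h_a, h_p, head_params) {
  dim_check <- function(h, nm) {
    if (length(h) != ncol(head_params[[paste0("W_", nm)]]))
      np_stop("np_shape_error", "embedding h_%s has length %d, expected %d",
              nm, length(h), ncol(head_params[[paste0("W_", nm)]]))
  }
  dim_check(h_v, "v"); dim_check(h_a, "a"); dim_check(h_p, "p")
  rows <- rbind(
    video  = stats::plogis(as.numeric(head_params$W_v %*% h_v + head_params$b_v)),
    audio  = stats::plogis(as.numeric(head_params$W_a %*% h_a + head_params$b_a)),
    physio = stats::plogis(as.numeric(head_params$W_p %*% h_p + head_params$b_p))
  )
  colnames(rows) <- concept_ids()
  present <- c(video = any(h_v != 0), audio = any(h_a != 0),
               physio = any(h_p != 0))
  src <- concept_modality()
  canonical <- vapply(seq_len(12), function(k) rows[src[k], k], numeric(1))
  list(matrix = rows,
       canonical = stats::setNames(canonical, concept_ids()),
       available = stats::setNames(unname(present[src]), concept_ids()))
}
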