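# Episode data model, on-disk bundle format, and standardized preprocessing.
#
# An episode is one synchronized multimodal clip: optional cry audio (mono,
# 16 kHz), optional physiological series (100 Hz: hr, spo2, rr, optional map;
# rows with negative time carry the 2-minute pre-clip baseline), optional
# facial action channels (30 fps, 4 channels in [0,1]), and context metadata.

AUDIO_RATE <- 16000L
PHYSIO_RATE <- 100L
FACIAL_RATE <- 30L
CLIP_SECONDS <- 10

#' Context metadata for one infant episode
#'
#' @param infant_id,site_id opaque identifiers
#' @param ga_weeks gestational age at birth, weeks; must lie in \[24, 44\]
#' @param postnatal_days postnatal age, days; must lie in \[0, 35\]
#' @param weight_g weight in grams
#' @param ventilated logical: mechanically ventilated / intubated
#' @param pain_label optional ordinal pain level in \{0, 1, 2, 3\}
#' @param concept_labels optional named vector of 12 binary concept labels
#' @return object of class `np_context_meta`
#' @export
context_meta <- function(infant_id, site_id = "site0", ga_weeks, postnatal_days,
                         weight_g, ventilated = FALSE, pain_label = NULL,
                         concept_labels = NULL) {
  if (!is.numeric(ga_weeks) || is.na(ga_weeks) || ga_weeks < 24 || ga_weeks > 44)
    np_stop("np_validation_error", "ga_weeks must lie in [24, 44], got %s",
            format(ga_weeks))
  if (!is.numeric(postnatal_days) || is.na(postnatal_days) ||
      postnatal_days < 0 || postnatal_days > 35)
    np_stop("np_validation_error", "postnatal_days must lie in [0, 35], got %s",
            format(postnatal_days))
  if (!is.null(pain_label) && !(pain_label %in% 0:3))
    np_stop("np_validation_error", "pain_label must be in {0,1,2,3}, got %s",
            format(pain_label))
  if (!is.null(concept_labels)) {
    if (length(concept_labels) != 12 || !all(concept_labels %in% c(0, 1)))
      np_stop("np_validation_error", "concept_labels must be 12 binary flags")
    concept_labels <- stats::setNames(as.integer(concept_labels), concept_ids())
  }
  structure(list(
    infant_id = as.character(infant_id), site_id = as.character(site_id),
    ga_weeks = as.numeric(ga_weeks), postnatal_days = as.numeric(postnatal_days),
    weight_g = as.numeric(weight_g), ventilated = isTRUE(ventilated),
    pain_label = if (is.null(pain_label)) NULL else as.integer(pain_label),
    concept_labels = concept_labels
  ), class = "np_context_meta")
}

#' Construct a multimodal episode
#'
#' At least one modality must be present. For a 10-second clip the present
#' streams must have exactly 160,000 audio samples, 1,000 physiological rows in
#' `[0, 10)` (rows with negative time are the pre-clip baseline history and are
#' allowed on top), and 300 facial rows.
#'
#' @param meta a [context_meta()]
#' @param audio optional numeric vector, mono 16 kHz, values in \[-1, 1\]
#' @param physio optional data.frame: `time` (s), `hr`, `spo2`, `rr`,
#'   optionally `map`; clip rows at 100 Hz, negative-time rows = baseline
#' @param facial optional data.frame: `time` plus channels `c1..c4` in \[0,1\]
#' @param duration_s clip duration in seconds
#' @return object of class `np_episode` with a `modality_mask`
#'   (video, audio, physio)
#' @export
episode <- function(meta, audio = NULL, physio = NULL, facial = NULL,
                    duration_s = CLIP_SECONDS) {
  stopifnot(inherits(meta, "np_context_meta"))
  mask <- c(video = !is.null(facial), audio = !is.null(audio),
            physio = !is.null(physio))
  if (!any(mask))
    np_stop("np_empty_episode_error", "episode has no modality present")
  if (!is.null(audio)) {
    audio <- as.numeric(audio)
    if (any(abs(audio) > 1 + 1e-9))
      np_stop("np_validation_error", "audio samples must lie in [-1, 1]")
    if (duration_s == CLIP_SECONDS && length(audio) != AUDIO_RATE * CLIP_SECONDS)
      np_stop("np_validation_error",
              "10-s clip must have exactly %d audio samples, got %d",
              AUDIO_RATE * CLIP_SECONDS, length(audio))
  }
  if (!is.null(physio)) {
    need <- c("time", "hr", "spo2", "rr")
    if (!all(need %in% names(physio)))
      np_stop("np_format_error", "physio must have columns time, hr, spo2, rr")
    n_clip <- sum(physio$time >= -1e-6 & physio$time < duration_s - 1e-6)
    if (duration_s == CLIP_SECONDS && n_clip != PHYSIO_RATE * CLIP_SECONDS)
      np_stop("np_validation_error",
              "10-s clip must have exactly %d physio rows in [0, 10), got %d",
              PHYSIO_RATE * CLIP_SECONDS, n_clip)
  }
  if (!is.null(facial)) {
    need <- c("time", paste0("c", 1:4))
    if (!all(need %in% names(facial)))
      np_stop("np_format_error", "facial must have columns time, c1..c4")
    vals <- as.matrix(facial[, paste0("c", 1:4)])
    if (any(vals < -1e-9 | vals > 1 + 1e-9))
      np_stop("np_validation_error", "facial channel values must lie in [0, 1]")
    if (duration_s == CLIP_SECONDS && nrow(facial) != FACIAL_RATE * CLIP_SECONDS)
      np_stop("np_validation_error",
              "10-s clip must have exactly %d facial rows, got %d",
              FACIAL_RATE * CLIP_SECONDS, nrow(facial))
  }
  structure(list(meta = meta, audio = audio, physio = physio, facial = facial,
                 modality_mask = mask, duration_s = as.numeric(duration_s)),
            class = "np_episode")
}

#' @export
print.np_episode <- function(x, ...) {
  cat(sprintf("<np_episode> infant %s, %.0f s, modalities: %s\n",
              x$meta$infant_id, x$duration_s,
              paste(names(x$modality_mask)[x$modality_mask], collapse = "+")))
  invisible(x)
}

meta_to_list <- function(meta) {
  out <- meta[!vapply(meta, is.null, logical(1))]
  unclass(out)
}

#' Write an episode bundle to disk
#'
#' The bundle is a directory with `meta.json` plus any of `audio.wav`,
#' `physio.csv`, `facial.csv`. Reading back is lossless for metadata and
#' lossless-to-quantization (float32 audio) for signals.
#'
#' @param ep an [episode()]
#' @param path bundle directory (created if needed)
#' @return `path`, invisibly
#' @export
write_bundle <- function(ep, path) {
  stopifnot(inherits(ep, "np_episode"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- meta_to_list(ep$meta)
  meta$duration_s <- ep$duration_s
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(ep$audio))
    write_wav(ep$audio, file.path(path, "audio.wav"), AUDIO_RATE)
  if (!is.null(ep$physio))
    utils::write.csv(ep$physio, file.path(path, "physio.csv"), row.names = FALSE)
  if (!is.null(ep$facial))
    utils::write.csv(ep$facial, file.path(path, "facial.csv"), row.names = FALSE)
  invisible(path)
}

#' Read an episode bundle from disk
#'
#' @param path bundle directory containing `meta.json` and at least one signal
#'   file; absent signal files clear the corresponding modality-mask bit
#' @return an [episode()]
#' @export
read_bundle <- function(path) {
  mf <- file.path(path, "meta.json")
  if (!file.exists(mf))
    np_stop("np_format_error", "bundle %s has no meta.json", path)
  m <- jsonlite::read_json(mf, simplifyVector = TRUE)
  meta <- context_meta(m$infant_id, m$site_id %||% "site0", m$ga_weeks,
                       m$postnatal_days, m$weight_g, isTRUE(m$ventilated),
                       m$pain_label, m$concept_labels)
  af <- file.path(path, "audio.wav")
  pf <- file.path(path, "physio.csv")
  ff <- file.path(path, "facial.csv")
  if (!any(file.exists(c(af, pf, ff))))
    np_stop("np_empty_episode_error", "bundle %s has no signal files", path)
  audio <- if (file.exists(af)) read_wav(af)$samples else NULL
  physio <- if (file.exists(pf)) utils::read.csv(pf) else NULL
  facial <- if (file.exists(ff)) utils::read.csv(ff) else NULL
  episode(meta, audio = audio, physio = physio, facial = facial,
          duration_s = m$duration_s %||% CLIP_SECONDS)
}

#' Standardized physiological preprocessing
#'
#' Wavelet denoising (Symlet-4, level-5 decomposition, soft universal
#' threshold), resampling to exactly 100 Hz (output timestamps are multiples of
#' 0.01 s), linear interpolation across gaps shorter than 2 s, and explicit NA
#' marking for gaps of 2 s or longer (never silently filled).
#'
#' @param raw data.frame with `time` (strictly increasing, seconds) and one or
#'   more numeric signal columns
#' @param raw_rate nominal sampling rate of the input, Hz
#' @return data.frame at 100 Hz with the same signal columns; unavailable
#'   segments are NA
#' @export
preprocess_physio <- function(raw, raw_rate) {
  if (!is.data.frame(raw) || !"time" %in% names(raw))
    np_stop("np_format_error", "raw series must be a data.frame with a time column")
  if (nrow(raw) < 2)
    np_stop("np_insufficient_data_error",
            "need at least 2 samples, got %d", nrow(raw))
  t <- raw$time
  if (any(diff(t) <= 0))
    np_stop("np_validation_error", "timestamps must be strictly increasing")
  gap_len <- diff(t)
  # Contiguous runs: split where consecutive samples are >= 2 s apart.
  run_id <- cumsum(c(0, gap_len >= 2))
  grid <- seq(ceiling(t[1] * PHYSIO_RATE), floor(t[length(t)] * PHYSIO_RATE)) / PHYSIO_RATE
  out <- data.frame(time = grid)
  sig_cols <- setdiff(names(raw), "time")
  # Grid points inside a >= 2 s gap stay NA.
  in_gap <- rep(FALSE, length(grid))
  for (k in which(gap_len >= 2)) {
    in_gap <- in_gap | (grid > t[k] & grid < t[k + 1])
  }
  for (col in sig_cols) {
    denoised <- numeric(length(t))
    for (r in unique(run_id)) {
      idx <- which(run_id == r)
      seg <- raw[[col]][idx]
      if (length(idx) >= 2) {
        # Regularize short (<2 s) intra-run gaps at the native rate first.
        tt <- t[idx]
        native <- seq(tt[1], tt[length(tt)], by = 1 / raw_rate)
        seg_u <- stats::approx(tt, seg, xout = native, rule = 2)$y
        seg_d <- wavelet_denoise(seg_u)
        denoised[idx] <- stats::approx(native, seg_d, xout = tt, rule = 2)$y
      } else {
        denoised[idx] <- seg
      }
    }
    y <- stats::approx(t, denoised, xout = grid, rule = 2)$y
    y[in_gap] <- NA_real_
    out[[col]] <- y
  }
  out
}

#' Segment an episode into overlapping 10-second clips
#'
#' Clips start at 0, 5, 10, ... seconds (50% overlap); each carries the parent
#' metadata and modality mask, with all present streams cut on the shared
#' timeline. Physiological rows earlier than a clip's start are retained as
#' that clip's (negative-time) baseline history. Episodes shorter than 10 s
#' yield zero clips and a warning.
#'
#' @param ep an [episode()]
#' @return list of 10-second [episode()] objects
#' @export
segment_clips <- function(ep) {
  stopifnot(inherits(ep, "np_episode"))
  if (ep$duration_s < CLIP_SECONDS) {
    np_warn("np_short_episode_warning",
            "episode of %.1f s is shorter than %d s; no clips produced",
            ep$duration_s, CLIP_SECONDS)
    return(list())
  }
  starts <- seq(0, ep$duration_s - CLIP_SECONDS, by = CLIP_SECONDS / 2)
  lapply(starts, function(s) {
    audio <- if (!is.null(ep$audio)) {
      ep$audio[(s * AUDIO_RATE + 1):((s + CLIP_SECONDS) * AUDIO_RATE)]
    }
    physio <- if (!is.null(ep$physio)) {
      ph <- ep$physio[ep$physio$time < s + CLIP_SECONDS, , drop = FALSE]
      ph$time <- ph$time - s
      ph
    }
    facial <- if (!is.null(ep$facial)) {
      fa <- ep$facial[ep$facial$time >= s - 1e-6 &
                      ep$facial$time < s + CLIP_SECONDS - 1e-6, , drop = FALSE]
      fa$time <- fa$time - s
      fa
    }
    episode(ep$meta, audio = audio, physio = physio, facial = facial,
            duration_s = CLIP_SECONDS)
  })
}
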