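# Episode data model, bundle round trips, preprocessing, segmentation.

test_that("bundle write/read round-trips a complete episode", {
  out <- fixture_episode(level = 2, seed = 11)
  dir <- withr::local_tempdir()
  write_bundle(out$episode, dir)
  back <- read_bundle(dir)
  expect_identical(back$meta$infant_id, out$episode$meta$infant_id)
  expect_identical(back$meta$ga_weeks, out$episode$meta$ga_weeks)
  expect_identical(back$meta$pain_label, out$episode$meta$pain_label)
  expect_identical(back$modality_mask, out$episode$modality_mask)
  # float32 audio: lossless to single-precision quantization
  expect_lt(max(abs(back$audio - out$episode$audio)), 1e-6)
  expect_equal(back$physio$hr, out$episode$physio$hr, tolerance = 1e-12)
  expect_equal(as.matrix(back$facial[, paste0("c", 1:4)]),
               as.matrix(out$episode$facial[, paste0("c", 1:4)]),
               tolerance = 1e-12)
})

test_that("round trips hold for 100 random episodes across mask combinations", {
  cfg <- synth_config(n_infants = 1, episodes_per_infant = 1, seed = 21)
  masks <- c("complete", "no_audio", "no_physio")
  set.seed(21)
  root <- withr::local_tempdir()
  ok_mask <- ok_sig <- logical(100)
  for (i in 1:100) {
    inf <- fixture_infant(ga_weeks = sample(c(26, 30, 35, 40), 1),
                          rho = stats::rnorm(1),
                          ventilated = i %% 10 == 0,
                          has_map = i %% 2 == 0)
    out <- synthesize_episode(inf, i %% 4, masks[(i %% 3) + 1], cfg,
                              seed = 300 + i, with_truth = FALSE)
    dir <- file.path(root, sprintf("b%03d", i))
    write_bundle(out$episode, dir)
    back <- read_bundle(dir)
    ok_mask[i] <- identical(back$modality_mask, out$episode$modality_mask) &&
      identical(back$meta$ga_weeks, out$episode$meta$ga_weeks) &&
      identical(back$meta$ventilated, out$episode$meta$ventilated)
    ok_sig[i] <-
      (is.null(back$audio) || max(abs(back$audio - out$episode$audio)) < 1e-6) &&
      (is.null(back$physio) ||
         isTRUE(all.equal(back$physio$hr, out$episode$physio$hr,
                          tolerance = 1e-12)))
    unlink(dir, recursive = TRUE)
  }
  expect_true(all(ok_mask))
  expect_true(all(ok_sig))
})

test_that("absent signal files clear the modality-mask bit", {
  out <- fixture_episode(seed = 31)
  dir <- withr::local_tempdir()
  write_bundle(out$episode, dir)
  file.remove(file.path(dir, "audio.wav"))
  back <- read_bundle(dir)
  expect_identical(unname(back$modality_mask), c(TRUE, FALSE, TRUE))
})

test_that("bundle and metadata validation errors are classed and named", {
  dir <- withr::local_tempdir()
  expect_np_error(read_bundle(dir), "np_format_error")
  out <- fixture_episode(seed = 41)
  write_bundle(out$episode, dir)
  for (f in c("audio.wav", "physio.csv", "facial.csv"))
    file.remove(file.path(dir, f))
  expect_np_error(read_bundle(dir), "np_empty_episode_error")
  expect_error(context_meta("I1", "s", ga_weeks = 50, postnatal_days = 3,
                            weight_g = 2000),
               "ga_weeks", class = "np_validation_error")
  expect_np_error(context_meta("I1", "s", 30, postnatal_days = 60,
                               weight_g = 2000), "np_validation_error")
  expect_np_error(context_meta("I1", "s", 30, 3, 2000, pain_label = 5),
                  "np_validation_error")
})

test_that("physio preprocessing fixes constants and uses an exact 100 Hz grid", {
  raw <- data.frame(time = seq(0, 9.99, by = 0.01), hr = 140)
  out <- preprocess_physio(raw, 100)
  expect_lt(max(abs(out$hr - 140)), 1e-6)
  expect_equal(out$time, round(out$time * 100) / 100, tolerance = 1e-12)
  k <- out$time * 100
  expect_lt(max(abs(k - round(k))), 1e-9)
})

test_that("short gaps are interpolated, long gaps are marked missing", {
  t1 <- seq(0, 4, by = 0.1)
  t2 <- seq(5.5, 9, by = 0.1)     # 1.5 s gap
  t3 <- seq(12, 15, by = 0.1)     # 3.0 s gap
  raw <- data.frame(time = c(t1, t2, t3), hr = 140)
  out <- preprocess_physio(raw, 10)
  in_short_gap <- out$time > 4 & out$time < 5.5
  in_long_gap <- out$time > 9 & out$time < 12
  expect_true(all(!is.na(out$hr[in_short_gap])))
  expect_lt(max(abs(out$hr[in_short_gap] - 140)), 1e-6)
  expect_true(all(is.na(out$hr[in_long_gap])))
})

test_that("preprocessing rejects degenerate input and is idempotent", {
  expect_np_error(preprocess_physio(data.frame(time = 1, hr = 140), 100),
                  "np_insufficient_data_error")
  tt <- seq(0, 9.99, by = 0.01)
  clean <- data.frame(time = tt, hr = 140 + 3 * sin(2 * pi * tt / 10))
  once <- preprocess_physio(clean, 100)
  twice <- preprocess_physio(once, 100)
  expect_lt(max(abs(once$hr - twice$hr), na.rm = TRUE), 1e-6)
})

test_that("mel spectrogram has the contracted shape and log floor", {
  m <- mel_spectrogram(numeric(160000))
  expect_identical(dim(m), c(128L, 155L))   # 1 + floor((160000-2048)/1024)
  expect_true(all(m == log(1e-10)))         # digital silence at the floor
  expect_np_error(mel_spectrogram(numeric(2000)),
                  "np_insufficient_data_error")
})

test_that("a pure tone concentrates energy at the matching mel band", {
  sr <- 16000
  tone <- sin(2 * pi * 1000 * seq(0, 10, length.out = sr * 10))
  m <- mel_spectrogram(tone)
  ctr <- attr(m, "center_hz")
  peak_band <- which.max(rowMeans(m))
  expect_identical(peak_band, which.min(abs(ctr - 1000)))
})

test_that("segmentation yields 50%-overlap clips with shared metadata", {
  cfg <- synth_config(n_infants = 1, episodes_per_infant = 1, seed = 55)
  base <- fixture_episode(level = 1, seed = 55)$episode
  # build a 30-s episode by tiling the 10-s clip on a common timeline
  audio <- rep(base$audio, 3)
  ph <- do.call(rbind, lapply(0:2, function(k) {
    p <- base$physio[base$physio$time >= 0, ]
    p$time <- p$time + 10 * k
    p
  }))
  fa <- do.call(rbind, lapply(0:2, function(k) {
    f <- base$facial
    f$time <- f$time + 10 * k
    f
  }))
  long <- episode(base$meta, audio = audio, physio = ph, facial = fa,
                  duration_s = 30)
  clips <- segment_clips(long)
  expect_length(clips, 5)                       # starts 0, 5, 10, 15, 20
  expect_true(all(vapply(clips, function(c) c$duration_s == 10, logical(1))))
  expect_true(all(vapply(clips, function(c)
    identical(c$meta$infant_id, long$meta$infant_id), logical(1))))
  expect_true(all(vapply(clips, function(c)
    identical(c$modality_mask, long$modality_mask), logical(1))))
  expect_length(segment_clips(base), 1)
  short <- episode(base$meta, audio = base$audio[1:(16000 * 9)],
                   duration_s = 9)
  expect_warning(res <- segment_clips(short),
                 class = "np_short_episode_warning")
  expect_length(res, 0)
})

test_that("clip count follows max(0, 1 + floor((d - 10)/5)) on a 0.1-s grid", {
  for (d in seq(0.5, 42, by = 3.7)) {
    expected <- max(0, 1 + floor((d - 10) / 5))
    n_a <- round(d * 16000)
    meta <- context_meta("I1", "s", 33, 5, 1800)
    ep <- episode(meta, audio = numeric(n_a), duration_s = d)
    got <- if (d < 10) {
      suppressWarnings(length(segment_clips(ep)))
    } else {
      length(segment_clips(ep))
    }
    expect_identical(got, as.integer(expected))
  }
})

test_that("WAV and Symlet-4 transforms round-trip", {
  w <- stats::runif(3200, -1, 1)
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(w, path, bits = 32L)
  r <- read_wav(path)
  expect_identical(r$sample_rate, 16000L)
  expect_lt(max(abs(r$samples - w)), 1e-6)
  write_wav(w, path, bits = 16L)
  expect_lt(max(abs(read_wav(path)$samples - w)), 1e-4)

  x <- sin(seq(0, 6 * pi, length.out = 256)) + 0.1 * stats::rnorm(256)
  expect_lt(max(abs(sym4_idwt(sym4_dwt(x, 5)) - x)), 1e-10)
  expect_lt(max(abs(wavelet_denoise(rep(87.5, 300)) - 87.5)), 1e-6)
})
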