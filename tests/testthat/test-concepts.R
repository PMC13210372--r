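# Threshold stratification and the 12 rule-based concept detectors.

test_that("GA strata resolve with half-open boundaries", {
  expect_equal(resolve_thresholds(ga_weeks = 26)$C1$activation, 0.60)
  expect_equal(resolve_thresholds(ga_weeks = 39)$C1$activation, 0.75)
  expect_equal(resolve_thresholds(ga_weeks = 28)$C1$activation, 0.65)
  expect_equal(resolve_thresholds(ga_weeks = 37)$C1$activation, 0.75)
  expect_equal(resolve_thresholds(ga_weeks = 36.9)$C6$f0_hz, 450)
  expect_equal(resolve_thresholds(ga_weeks = 37)$C6$f0_hz, 500)
  expect_np_error(resolve_thresholds(ga_weeks = 23), "np_validation_error")
  expect_np_error(resolve_thresholds(ga_weeks = 45), "np_validation_error")
})

test_that("threshold table validates stratum monotonicity and YAML round-trips", {
  tab <- default_thresholds()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_thresholds_yaml(tab, path)
  back <- read_thresholds_yaml(path)
  expect_equal(back$C1$strata, tab$C1$strata)
  expect_equal(back$C9$rel_increase, tab$C9$rel_increase)
  bad <- tab
  bad$C1$strata <- c(lt28 = 0.75, s28to32 = 0.65, s32to37 = 0.70, ge37 = 0.60)
  expect_np_error(resolve_thresholds(bad, 30), "np_validation_error")
})

test_that("cry F0 firing respects the preterm/term split", {
  term_thr <- resolve_thresholds(ga_weeks = 39)
  pre_thr <- resolve_thresholds(ga_weeks = 30)
  at <- function(f0, ga, thr) detect_vocal_concepts(
    harmonic_stack(f0), ga, thr)
  expect_true(at(520, 39, term_thr)$fired[2])    # C6 fires at term
  expect_false(at(470, 39, term_thr)$fired[2])   # below term threshold
  expect_true(at(470, 30, pre_thr)$fired[2])     # fires preterm
})

test_that("cry intensity needs sustained vocalization above the RMS limit", {
  thr <- resolve_thresholds(ga_weeks = 39)
  loud <- detect_vocal_concepts(harmonic_stack(450, rms = 0.4, burst_s = 0.8),
                                39, thr)
  expect_true(loud$fired[1])
  quiet <- detect_vocal_concepts(harmonic_stack(450, rms = 0.2, burst_s = 0.8),
                                 39, thr)
  expect_false(quiet$fired[1])
  brief <- detect_vocal_concepts(harmonic_stack(450, rms = 0.4, burst_s = 0.4,
                                                pause_s = 0.1),
                                 39, thr)
  expect_false(brief$fired[1])                   # no run longer than 500 ms
})

test_that("silence leaves the vocal concepts inactive and pauses need a cry", {
  thr <- resolve_thresholds(ga_weeks = 39)
  silent <- detect_vocal_concepts(numeric(32000), 39, thr)
  expect_false(any(silent$fired))
  expect_equal(silent$activation, rep(0, 4))
  expect_true(all(silent$available))
  absent <- detect_vocal_concepts(NULL, 39, thr)
  expect_false(any(absent$available))
  long_pause <- detect_vocal_concepts(
    harmonic_stack(420, seconds = 3, pause_s = 0.35), 39, thr)
  expect_true(long_pause$fired[4])               # C8: pause > 200 ms
})

test_that("HR concept fires on relative or absolute branches", {
  thr <- default_thresholds()
  hr_step <- function(base, clip) function(t) ifelse(t < 0, base, clip)
  r <- detect_physio_concepts(physio_frame(hr = hr_step(150, 180)), thr)
  expect_true(r$fired[1])                        # +20% relative
  r <- detect_physio_concepts(physio_frame(hr = hr_step(150, 160)), thr)
  expect_false(r$fired[1])                       # +6.7%, under 180
  r <- detect_physio_concepts(physio_frame(hr = hr_step(170, 182)), thr)
  expect_true(r$fired[1])                        # absolute branch
})

test_that("SpO2 concept fires on drops or absolute desaturation", {
  thr <- default_thresholds()
  r <- detect_physio_concepts(physio_frame(spo2 = 91), thr)
  expect_true(r$fired[2])                        # steady 91% < 92%
  dip <- function(t) ifelse(t >= 2 & t <= 8, 97 - 5, 97)
  r <- detect_physio_concepts(physio_frame(spo2 = dip), thr)
  expect_true(r$fired[2])                        # 5-point drop within 30 s
  r <- detect_physio_concepts(physio_frame(spo2 = 97), thr)
  expect_false(r$fired[2])
})

test_that("RR variability and MAP concepts behave per their rules", {
  thr <- default_thresholds()
  wiggly <- function(t) 45 + 45 * 0.35 * sqrt(2) * sin(2 * pi * t / 6)
  r <- detect_physio_concepts(physio_frame(rr = wiggly), thr)
  expect_true(r$fired[3])                        # CV ~ 0.35 > 0.25
  r <- detect_physio_concepts(physio_frame(), thr)
  expect_false(r$fired[3])
  expect_false(r$available[4])                   # no MAP column
  map_step <- function(t) ifelse(t < 0, 45, 57)
  r <- detect_physio_concepts(physio_frame(map = map_step), thr)
  expect_true(r$available[4])
  expect_true(r$fired[4])                        # +12 mmHg
  r <- detect_physio_concepts(physio_frame(map = 45), thr)
  expect_false(r$fired[4])
})

test_that("degraded baselines warn but still compute", {
  thr <- default_thresholds()
  short <- physio_frame(from = -10)
  expect_warning(r <- detect_physio_concepts(short, thr),
                 class = "np_degraded_baseline_warning")
  expect_length(r$fired, 4)
})

test_that("facial concepts use the stratified 90th-percentile rule", {
  n <- 300
  mk <- function(v) data.frame(time = (0:(n - 1)) / 30, c1 = v, c2 = 0,
                               c3 = 0, c4 = 0)
  term <- resolve_thresholds(ga_weeks = 39)
  pre <- resolve_thresholds(ga_weeks = 26)
  expect_true(detect_facial_concepts(mk(0.8), 39, term)$fired[1])
  expect_false(detect_facial_concepts(mk(0.72), 39, term)$fired[1])
  expect_true(detect_facial_concepts(mk(0.65), 26, pre)$fired[1])
  zero <- detect_facial_concepts(mk(0), 39, term)
  expect_false(any(zero$fired))
  expect_false(any(detect_facial_concepts(NULL, 39, term)$available))
})

test_that("facial firing is monotone in the GA threshold", {
  # any clip firing at the term threshold fires at every lower-GA threshold
  set.seed(42)
  n <- 300
  for (rep in 1:20) {
    vals <- stats::runif(1, 0.5, 1) +
      stats::rnorm(n, 0, 0.05)
    df <- data.frame(time = (0:(n - 1)) / 30, c1 = pmin(pmax(vals, 0), 1),
                     c2 = 0, c3 = 0, c4 = 0)
    fired <- vapply(c(39, 34, 30, 26), function(ga)
      detect_facial_concepts(df, ga, resolve_thresholds(ga_weeks = ga))$fired[1],
      logical(1))
    if (fired[1]) expect_true(all(fired))
    expect_true(all(diff(fired) >= 0 | !fired[1]))
  }
})

test_that("activations stay in [0,1] for arbitrary finite inputs", {
  set.seed(7)
  thr <- default_thresholds()
  for (i in 1:10) {
    ph <- physio_frame(hr = function(t) 140 + 80 * sin(t) + i * 10,
                       spo2 = function(t) pmin(pmax(97 - i * sin(t / 3), 0), 100),
                       rr = function(t) 45 + i * 2 * sin(2 * pi * t / 6),
                       map = function(t) 45 + i * sin(t / 5))
    r <- suppressWarnings(detect_physio_concepts(ph, thr))
    expect_true(all(r$activation >= 0 & r$activation <= 1))
    w <- stats::runif(32000, -1, 1) * (i / 10)
    v <- detect_vocal_concepts(w, 39, resolve_thresholds(ga_weeks = 39))
    expect_true(all(v$activation >= 0 & v$activation <= 1))
  }
})

test_that("concept heads project, saturate and select canonically", {
  d <- 128
  zero_heads <- list(W_v = matrix(0, 12, d), W_a = matrix(0, 12, d),
                     W_p = matrix(0, 12, d), b_v = numeric(12),
                     b_a = numeric(12), b_p = numeric(12))
  r <- concept_heads_forward(rep(1, d), rep(1, d), rep(1, d), zero_heads)
  expect_true(all(r$matrix == 0.5))
  hot <- zero_heads
  hot$b_v <- rep(20, 12)
  r <- concept_heads_forward(rep(1, d), rep(1, d), rep(1, d), hot)
  expect_true(all(r$matrix["video", ] > 0.999))
  set.seed(9)
  rnd <- list(W_v = matrix(rnorm(12 * d), 12, d),
              W_a = matrix(rnorm(12 * d), 12, d),
              W_p = matrix(rnorm(12 * d), 12, d),
              b_v = rnorm(12), b_a = rnorm(12), b_p = rnorm(12))
  h_v <- rnorm(d); h_a <- rnorm(d); h_p <- rnorm(d)
  r <- concept_heads_forward(h_v, h_a, h_p, rnd)
  src <- rep(c("video", "audio", "physio"), each = 4)
  for (k in 1:12) expect_identical(unname(r$canonical[k]), r$matrix[src[k], k])
  r0 <- concept_heads_forward(h_v, numeric(d), h_p, rnd)
  expect_false(any(r0$available[5:8]))
  expect_np_error(concept_heads_forward(rnorm(64), h_a, h_p, rnd),
                  "np_shape_error")
})
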