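# Shared fixtures, built in code and memoized across test files.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, builder(), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# A typical term infant (rho = 0) used for deterministic signal examples.
fixture_infant <- function(ga_weeks = 39, rho = 0, ventilated = FALSE,
                           has_map = TRUE) {
  list(infant_id = "IT001", ga_weeks = ga_weeks, postnatal_days = 7,
       weight_g = 3100, ventilated = ventilated, rho = rho,
       hr_base = 140, spo2_base = 97, rr_base = 45, map_base = 45,
       has_map = has_map)
}

# One complete synthetic episode at the given pain level (default noise).
fixture_episode <- function(level = 2, seed = 101, noise = 1,
                            ga_weeks = 39, rho = 0, ventilated = FALSE) {
  cfg <- synth_config(n_infants = 1, episodes_per_infant = 1,
                      noise_scale = noise, seed = seed)
  synthesize_episode(fixture_infant(ga_weeks, rho, ventilated), level,
                     "complete", cfg, seed = seed)
}

# A pure harmonic cry-like stack at a chosen F0 (for vocal concept tests).
harmonic_stack <- function(f0, seconds = 2, rms = 0.4, sr = 16000,
                           burst_s = 0.8, pause_s = 0.3) {
  t <- seq(0, seconds - 1 / sr, by = 1 / sr)
  x <- rowSums(vapply(1:6, function(h) (0.6^h) * sin(2 * pi * h * f0 * t),
                      numeric(length(t))))
  x <- x / sqrt(mean(x^2)) * rms
  cycle <- burst_s + pause_s
  x[(t %% cycle) >= burst_s] <- 0
  x
}

# Small default-noise cohort shared by fusion/learning tests (fast).
small_cohort <- function() {
  memo("small_cohort", function() {
    cfg <- synth_config(n_infants = 24, episodes_per_infant = 4, seed = 400)
    cohort_concepts(cfg, with_truth = FALSE)
  })
}

# A quickly trained model over the small cohort (for contract tests that
# need non-degenerate evidence; accuracy is not asserted on this one).
small_model <- function() {
  memo("small_model", function() {
    co <- small_cohort()
    train_pipeline(co$concepts, co$meta$pain_level,
                   config = train_config(epochs = 15, lr = 0.3, seed = 5))
  })
}

# A 100 Hz physiological data.frame with a 2-minute baseline, constant
# values unless overridden by functions of time.
physio_frame <- function(hr = 140, spo2 = 97, rr = 45, map = NULL,
                         from = -120, to = 10) {
  t <- seq(from, to - 0.01, by = 0.01)
  f <- function(v) if (is.function(v)) v(t) else rep(v, length(t))
  df <- data.frame(time = t, hr = f(hr), spo2 = f(spo2), rr = f(rr))
  if (!is.null(map)) df$map <- f(map)
  df
}

expect_np_error <- function(expr, class) {
  expect_error(expr, class = class)
}

# Independent textbook weighted-kappa oracle (explicit double loops).
kappa_oracle <- function(y_true, y_pred, weights = "quadratic", K = 4) {
  n <- length(y_true)
  O <- matrix(0, K, K)
  for (i in seq_len(n)) O[y_true[i] + 1, y_pred[i] + 1] <-
      O[y_true[i] + 1, y_pred[i] + 1] + 1
  E <- matrix(0, K, K)
  for (a in 1:K) for (b in 1:K) E[a, b] <- sum(O[a, ]) * sum(O[, b]) / n
  W <- matrix(0, K, K)
  for (a in 1:K) for (b in 1:K) {
    W[a, b] <- if (weights == "quadratic") ((a - b)^2) / ((K - 1)^2)
               else abs(a - b) / (K - 1)
  }
  den <- sum(W * E)
  if (den == 0) return(1)
  1 - sum(W * O) / den
}
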