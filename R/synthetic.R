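# Synthetic multimodal NICU episode generator with known ground truth.
#
# Every generative constant is a package choice (exposed in synth_config),
# calibrated once so that clean signals decisively clear or miss the clinical
# concept thresholds. Ground-truth concept labels are obtained by running the
# rule-based detectors on the clean (pre-measurement-noise) signals, so at
# zero noise the detectors agree with the labels exactly by construction.

#' Synthetic cohort configuration
#'
#' Defaults encode the study conditions the generator emulates: GA stratum mix
#' 15/35/30/20% (<28 / 28-32 / 32-37 / >=37 w), pain level mix 25/30/25/20%,
#' modality availability 75% complete / 15% missing audio / 10% missing
#' physiological, 5% ventilated infants (who emit no audio), MAP recorded with
#' probability 0.7, per-infant expressivity SD 0.8 on the logit scale.
#'
#' @param n_infants number of infants
#' @param episodes_per_infant episodes per infant
#' @param ga_props proportions for the four GA strata (sum to 1)
#' @param pain_props proportions for pain levels 0..3 (sum to 1)
#' @param modality_props proportions complete / missing-audio / missing-physio
#' @param ventilated_frac fraction of ventilated infants
#' @param map_prob probability that the MAP channel is recorded
#' @param expressivity_sd SD of the per-infant expressivity effect rho
#' @param noise_scale global multiplier on all measurement noise (0 = clean)
#' @param seed RNG seed
#' @return object of class `np_synth_config`
#' @export
synth_config <- function(n_infants = 200L, episodes_per_infant = 4L,
                         ga_props = c(0.15, 0.35, 0.30, 0.20),
                         pain_props = c(0.25, 0.30, 0.25, 0.20),
                         modality_props = c(complete = 0.75, no_audio = 0.15,
                                            no_physio = 0.10),
                         ventilated_frac = 0.05, map_prob = 0.7,
                         expressivity_sd = 1.0, noise_scale = 1.0,
                         seed = 1L) {
  for (p in list(ga_props, pain_props, modality_props)) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
      np_stop("np_validation_error",
              "proportions must be non-negative and sum to 1")
  }
  if (noise_scale < 0 || expressivity_sd < 0)
    np_stop("np_validation_error", "scales must be non-negative")
  structure(list(
    n_infants = as.integer(n_infants),
    episodes_per_infant = as.integer(episodes_per_infant),
    ga_props = ga_props, pain_props = pain_props,
    modality_props = modality_props, ventilated_frac = ventilated_frac,
    map_prob = map_prob, expressivity_sd = expressivity_sd,
    noise_scale = noise_scale, seed = as.integer(seed)
  ), class = "np_synth_config")
}

GA_BOUNDS <- list(lt28 = c(24, 28), s28to32 = c(28, 32),
                  s32to37 = c(32, 37), ge37 = c(37, 44))

#' Sample a cohort plan
#'
#' Draws per-infant gestational age (within stratum), postnatal age (uniform
#' 0-35 d), weight, ventilation status, expressivity `rho ~ N(0, sd^2)` and
#' physiological baselines, then per-episode pain levels and modality masks.
#' Fully reproducible from the config seed.
#'
#' @param config a [synth_config()]
#' @return list with data.frames `infants` and `episodes`
#' @export
sample_cohort <- function(config) {
  stopifnot(inherits(config, "np_synth_config"))
  with_seed(derive_seed(config$seed, 1L), {
    n <- config$n_infants
    strat <- sample(GA_STRATA, n, replace = TRUE, prob = config$ga_props)
    ga <- vapply(strat, function(s) {
      b <- GA_BOUNDS[[s]]
      stats::runif(1, b[1], min(b[2], 44) - 1e-6)
    }, numeric(1))
    infants <- data.frame(
      infant_id = sprintf("I%04d", seq_len(n)),
      ga_weeks = round(ga, 1),
      postnatal_days = round(stats::runif(n, 0, 35), 1),
      weight_g = round(clamp(1000 + 150 * (ga - 28) +
                               stats::rnorm(n, 0, 150), 450, 4800)),
      ventilated = stats::runif(n) < config$ventilated_frac,
      rho = stats::rnorm(n, 0, config$expressivity_sd),
      hr_base = stats::rnorm(n, 140, 10),
      spo2_base = 97,
      rr_base = stats::rnorm(n, 45, 3),
      map_base = stats::rnorm(n, 45, 4),
      has_map = stats::runif(n) < config$map_prob,
      stringsAsFactors = FALSE
    )
    m <- config$episodes_per_infant
    episodes <- data.frame(
      infant_id = rep(infants$infant_id, each = m),
      episode_id = sprintf("E%05d", seq_len(n * m)),
      pain_level = sample(0:3, n * m, replace = TRUE, prob = config$pain_props),
      modality = sample(names(config$modality_props), n * m, replace = TRUE,
                        prob = config$modality_props),
      stringsAsFactors = FALSE
    )
    vent <- infants$ventilated[match(episodes$infant_id, infants$infant_id)]
    episodes$modality[vent & episodes$modality == "complete"] <- "no_audio"
    episodes$seed <- derive_seed(config$seed, 100L + seq_len(n * m))
    list(infants = infants, episodes = episodes)
  })
}

# ---- signal renderers -------------------------------------------------------
# Each returns clean and noisy versions; "clean" = no measurement noise.

ar1_noise <- function(n, sd, phi = 0.95) {
  if (sd <= 0) return(numeric(n))
  as.numeric(stats::filter(stats::rnorm(n, 0, sd * sqrt(1 - phi^2)),
                           phi, method = "recursive"))
}

# Per-infant pain reactivity: a single lognormal multiplier on every
# pain-driven response, derived from the expressivity effect rho. This is
# the latent trait personalization must recover: a weak reactor at severe
# pain resembles a typical infant at moderate pain on any single clip.
reactivity <- function(infant) exp(0.25 * infant$rho)

render_physio <- function(infant, level, config) {
  ns <- config$noise_scale
  m <- reactivity(infant)
  t <- seq(-120, 10 - 1 / PHYSIO_RATE, by = 1 / PHYSIO_RATE)
  n <- length(t)
  clip <- t >= 0

  hr_clean <- rep(infant$hr_base, n)
  hr_clean[clip] <- infant$hr_base * (1 + 0.07 * m * level)
  hr_noisy <- hr_clean + ar1_noise(n, 1.5 * ns)

  dip <- pmax(0, 2.6 * m * level)
  spo2_clean <- rep(infant$spo2_base, n)
  # half-cosine desaturation centred in the clip
  win <- t >= 2 & t <= 8
  spo2_clean[win] <- infant$spo2_base -
    dip * 0.5 * (1 - cos(2 * pi * (t[win] - 2) / 6))
  spo2_noisy <- clamp(spo2_clean + ar1_noise(n, 0.25 * ns, 0.9), 0, 100)

  # respiratory irregularity over the trailing minute (pain state spans the
  # scoring clip and its immediate lead-in)
  cv_target <- 0.05 + 0.09 * m * level
  cv_base <- 0.05
  amp <- sqrt(2) * infant$rr_base
  osc <- sin(2 * pi * (t + 120) / 6)
  rr_clean <- infant$rr_base + amp * osc *
    ifelse(t >= -50, cv_target, cv_base)
  rr_noisy <- pmax(rr_clean + ar1_noise(n, 0.5 * ns, 0.8), 1)

  map_inc <- 3.8 * m * level
  map_clean <- rep(infant$map_base, n)
  map_clean[clip] <- infant$map_base + map_inc
  map_noisy <- map_clean + ar1_noise(n, 1.0 * ns, 0.9)

  clean <- data.frame(time = t, hr = hr_clean, spo2 = spo2_clean,
                      rr = rr_clean)
  noisy <- data.frame(time = t, hr = hr_noisy, spo2 = spo2_noisy,
                      rr = rr_noisy)
  if (isTRUE(infant$has_map)) {
    clean$map <- map_clean
    noisy$map <- map_noisy
  }
  list(clean = clean, noisy = noisy)
}

render_audio <- function(infant, level, config, sr = AUDIO_RATE) {
  ns <- config$noise_scale
  n <- sr * CLIP_SECONDS
  floor_amp <- 0.002
  if (level == 0 || isTRUE(infant$ventilated)) {
    clean <- rep(0, n)
    noisy <- floor_amp * ns * stats::rnorm(n)
    return(list(clean = clean, noisy = clamp(noisy, -1, 1)))
  }
  m <- reactivity(infant)
  f0 <- 380 + 45 * m * level + 10 * (infant$ga_weeks >= 37)
  rms_target <- clamp(0.1 + 0.12 * m * level, 0.02, 0.9)
  h_frac <- clamp(1.0 - 0.25 * m * level, 0.05, 1) # harmonic power fraction
  burst_s <- 1.0
  pause_s <- (0.10 + 0.08 * level) * exp(0.15 * infant$rho)
  tt <- seq(0, CLIP_SECONDS - 1 / sr, by = 1 / sr)
  cycle <- burst_s + pause_s
  in_burst <- (tt %% cycle) < burst_s
  harm <- rowSums(vapply(1:6, function(h)
    (0.6^h) * sin(2 * pi * h * f0 * tt + h), numeric(n)))
  harm <- harm / sqrt(mean(harm^2))
  turb <- stats::rnorm(n)
  voice <- sqrt(h_frac) * harm + sqrt(1 - h_frac) * turb
  clean <- numeric(n)
  clean[in_burst] <- voice[in_burst] * rms_target
  clean <- clamp(clean, -1, 1)
  noisy <- clamp(clean + 0.01 * ns * stats::rnorm(n), -1, 1)
  list(clean = clean, noisy = noisy)
}

render_facial <- function(infant, level, config) {
  ns <- config$noise_scale
  n <- FACIAL_RATE * CLIP_SECONDS
  t <- (seq_len(n) - 1) / FACIAL_RATE
  ga_eff <- switch(ga_stratum(infant$ga_weeks),
                   lt28 = -0.7, s28to32 = -0.35, s32to37 = -0.1, ge37 = 0.2)
  b_ch <- c(-1.4, -1.8, -2.2, -2.6)
  mu <- stats::plogis(1.5 * reactivity(infant) * level + b_ch +
                        0.3 * infant$rho + ga_eff)
  clean <- vapply(mu, function(m) rep(m, n), numeric(n))
  noise <- vapply(1:4, function(i) {
    raw <- stats::rnorm(n + 4, 0, 0.04 * ns)
    as.numeric(stats::filter(raw, rep(1 / 5, 5), sides = 2))[3:(n + 2)]
  }, numeric(n))
  noisy <- clamp(clean + noise, 0, 1)
  to_df <- function(m) {
    df <- as.data.frame(m)
    names(df) <- paste0("c", 1:4)
    cbind(time = t, df)
  }
  list(clean = to_df(clamp(clean, 0, 1)), noisy = to_df(noisy))
}

#' Synthesize one multimodal episode with ground truth
#'
#' Renders clean and measurement-noise versions of all three modality streams,
#' emits an [episode()] restricted to the requested modality mask (ventilated
#' infants emit no audio), and computes ground-truth concept labels by running
#' the rule-based detectors on the clean, fully observed signals.
#'
#' @param infant one row of the `infants` table from [sample_cohort()] (as a
#'   list or single-row data.frame)
#' @param pain_level ordinal pain level 0..3
#' @param mask "complete", "no_audio" or "no_physio"
#' @param config a [synth_config()]
#' @param seed per-episode RNG seed
#' @param with_truth compute ground-truth concept labels (default TRUE)
#' @return list with `episode` (noisy, masked), `truth` (named integer concept
#'   labels + pain level), and `clean` (the clean fully-observed episode)
#' @export
synthesize_episode <- function(infant, pain_level, mask, config,
                               seed = config$seed, with_truth = TRUE) {
  if (!pain_level %in% 0:3)
    np_stop("np_validation_error", "pain_level must be in 0..3")
  infant <- as.list(infant)
  with_seed(seed, {
    ph <- render_physio(infant, pain_level, config)
    au <- render_audio(infant, pain_level, config)
    fa <- render_facial(infant, pain_level, config)

    meta <- context_meta(infant$infant_id, infant$site_id %||% "site0",
                         infant$ga_weeks, infant$postnatal_days,
                         infant$weight_g, infant$ventilated,
                         pain_label = pain_level)
    audio_out <- if (mask != "no_audio" && !isTRUE(infant$ventilated))
      au$noisy else NULL
    physio_out <- if (mask != "no_physio") ph$noisy else NULL
    ep <- episode(meta, audio = audio_out, physio = physio_out,
                  facial = fa$noisy)

    clean_ep <- episode(meta, audio = au$clean, physio = ph$clean,
                        facial = fa$clean)
    truth <- NULL
    if (with_truth) {
      cv <- detect_concepts(clean_ep)
      truth <- list(pain_level = pain_level,
                    concept_labels = as.integer(cv$fired),
                    rho = infant$rho)
    }
    list(episode = ep, truth = truth, clean = clean_ep)
  })
}

#' Generate a full cohort of concept-level observations
#'
#' Streams episode synthesis: each episode is rendered, passed through the
#' rule-based detectors, and reduced to its concept vector, so the raw signals
#' never accumulate in memory. This is the workhorse behind training,
#' evaluation and the federated simulator.
#'
#' @param config a [synth_config()]
#' @param with_truth include ground-truth labels
#' @param progress print progress every 100 episodes
#' @return list: `plan` (from [sample_cohort()]), `concepts` (list of
#'   `np_concept_vector`), `meta` (data.frame with infant, GA, ventilated,
#'   pain level, modality mask), `truth` (12-col 0/1 matrix or NULL)
#' @export
cohort_concepts <- function(config, with_truth = TRUE, progress = FALSE) {
  plan <- sample_cohort(config)
  eps <- plan$episodes
  inf <- plan$infants
  n <- nrow(eps)
  concepts <- vector("list", n)
  truth <- if (with_truth) matrix(NA_integer_, n, 12,
                                  dimnames = list(NULL, concept_ids()))
  for (i in seq_len(n)) {
    row <- inf[match(eps$infant_id[i], inf$infant_id), ]
    out <- synthesize_episode(row, eps$pain_level[i], eps$modality[i],
                              config, seed = eps$seed[i],
                              with_truth = with_truth)
    concepts[[i]] <- suppressWarnings(detect_concepts(out$episode))
    if (with_truth) truth[i, ] <- out$truth$concept_labels
    if (progress && i %% 100 == 0) message(sprintf("  %d / %d episodes", i, n))
  }
  meta <- data.frame(
    infant_id = eps$infant_id, episode_id = eps$episode_id,
    ga_weeks = inf$ga_weeks[match(eps$infant_id, inf$infant_id)],
    ventilated = inf$ventilated[match(eps$infant_id, inf$infant_id)],
    rho = inf$rho[match(eps$infant_id, inf$infant_id)],
    pain_level = eps$pain_level, modality = eps$modality,
    stringsAsFactors = FALSE
  )
  list(plan = plan, concepts = concepts, meta = meta, truth = truth)
}

#' Write a cohort of episode bundles to disk
#'
#' Emits one bundle directory per episode plus `ground_truth.csv` and a cohort
#' `manifest.json`.
#'
#' @param config a [synth_config()]
#' @param out_dir output directory
#' @param with_truth write ground-truth labels
#' @return `out_dir`, invisibly
#' @export
write_cohort <- function(config, out_dir, with_truth = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  plan <- sample_cohort(config)
  eps <- plan$episodes
  inf <- plan$infants
  gt <- NULL
  for (i in seq_len(nrow(eps))) {
    row <- inf[match(eps$infant_id[i], inf$infant_id), ]
    out <- synthesize_episode(row, eps$pain_level[i], eps$modality[i],
                              config, seed = eps$seed[i],
                              with_truth = with_truth)
    write_bundle(out$episode, file.path(out_dir, eps$episode_id[i]))
    if (with_truth) {
      rec <- data.frame(episode_id = eps$episode_id[i],
                        infant_id = eps$infant_id[i],
                        pain_level = eps$pain_level[i],
                        modality = eps$modality[i])
      labs <- as.data.frame(t(out$truth$concept_labels))
      names(labs) <- concept_ids()
      gt <- rbind(gt, cbind(rec, labs))
    }
  }
  if (with_truth)
    utils::write.csv(gt, file.path(out_dir, "ground_truth.csv"),
                     row.names = FALSE)
  jsonlite::write_json(
    list(n_infants = config$n_infants,
         episodes = nrow(eps), seed = config$seed,
         noise_scale = config$noise_scale),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE)
  invisible(out_dir)
}
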