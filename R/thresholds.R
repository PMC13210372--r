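# Gestational-age-stratified clinical thresholds for the 12 concepts.
#
# GA strata: [24,28) extremely preterm, [28,32) very preterm, [32,37)
# moderate/late preterm, [37,44] term. Facial activation thresholds rise with
# maturity (0.60 -> 0.75) because facial muscle control is underdeveloped in
# extremely preterm infants; cry F0 uses 450 Hz (preterm) vs 500 Hz (term).

GA_STRATA <- c("lt28", "s28to32", "s32to37", "ge37")

ga_stratum <- function(ga_weeks) {
  if (is.na(ga_weeks) || ga_weeks < 24 || ga_weeks > 44)
    np_stop("np_validation_error", "ga_weeks must lie in [24, 44], got %s",
            format(ga_weeks))
  if (ga_weeks < 28) "lt28"
  else if (ga_weeks < 32) "s28to32"
  else if (ga_weeks < 37) "s32to37"
  else "ge37"
}

#' Default clinical threshold table
#'
#' Facial concepts C1-C4 fire on activation above a stratified threshold
#' (0.60 / 0.65 / 0.70 / 0.75 from extremely preterm to term; default 0.70).
#' Vocal and physiological concepts use the clinical criteria in their native
#' units: C5 RMS > 0.3 sustained > 500 ms; C6 F0 > 450 Hz preterm / 500 Hz
#' term; C7 HNR < 0.5 with spectral irregularity > 0.3; C8 pause > 200 ms
#' within a cry episode; C9 HR +15% over the 2-min baseline or > 180 bpm;
#' C10 SpO2 drop > 4 points within 30 s or < 92%; C11 respiratory-rate CV
#' > 0.25 over 1 min; C12 MAP +10 mmHg over baseline.
#'
#' @return object of class `np_threshold_table`
#' @export
default_thresholds <- function() {
  facial <- list(default = 0.70,
                 strata = c(lt28 = 0.60, s28to32 = 0.65, s32to37 = 0.70,
                            ge37 = 0.75))
  tab <- list(
    C1 = facial, C2 = facial, C3 = facial, C4 = facial,
    C5 = list(rms = 0.3, sustained_s = 0.5),
    C6 = list(f0_hz = c(lt28 = 450, s28to32 = 450, s32to37 = 450, ge37 = 500)),
    C7 = list(hnr = 0.5, irregularity = 0.3),
    C8 = list(pause_s = 0.2),
    C9 = list(rel_increase = 0.15, abs_bpm = 180),
    C10 = list(drop_points = 4, window_s = 30, abs_pct = 92),
    C11 = list(cv = 0.25, window_s = 60),
    C12 = list(increase_mmhg = 10)
  )
  structure(tab, class = "np_threshold_table")
}

validate_threshold_table <- function(tab) {
  if (!all(concept_ids() %in% names(tab)))
    np_stop("np_validation_error", "threshold table must cover C1..C12")
  for (k in paste0("C", 1:4)) {
    s <- tab[[k]]$strata[GA_STRATA]
    if (any(is.na(s)))
      np_stop("np_validation_error", "%s must define all four GA strata", k)
    if (any(diff(s) < 0))
      np_stop("np_validation_error",
              "%s facial thresholds must be non-decreasing in GA", k)
    if (any(abs(s - tab[[k]]$default) > 0.15 + 1e-9))
      np_stop("np_validation_error",
              "%s stratum values must lie within 0.15 of the default", k)
  }
  invisible(tab)
}

#' Resolve per-concept thresholds for one infant
#'
#' @param table an `np_threshold_table`; see [default_thresholds()]
#' @param ga_weeks gestational age in \[24, 44\]; stratum boundaries are
#'   half-open: 28 weeks falls in the 28-32 stratum
#' @return named list of per-concept thresholds with the stratified entries
#'   (facial activation, cry F0) collapsed to this infant's values
#' @export
resolve_thresholds <- function(table = default_thresholds(), ga_weeks) {
  validate_threshold_table(table)
  stratum <- ga_stratum(ga_weeks)
  out <- table
  for (k in paste0("C", 1:4)) {
    out[[k]] <- list(activation = unname(table[[k]]$strata[stratum]))
  }
  out$C6 <- list(f0_hz = unname(table$C6$f0_hz[stratum]))
  attr(out, "stratum") <- stratum
  attr(out, "ga_weeks") <- ga_weeks
  out
}

#' Write / read a threshold table as YAML
#' @param tab an `np_threshold_table`
#' @param path YAML file path
#' @return `path` invisibly (write) or the table (read)
#' @export
write_thresholds_yaml <- function(tab, path) {
  validate_threshold_table(tab)
  yaml::write_yaml(lapply(unclass(tab), function(x)
    lapply(x, function(v) if (is.null(names(v))) v else as.list(v))), path)
  invisible(path)
}

#' @rdname write_thresholds_yaml
#' @export
read_thresholds_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  tab <- lapply(raw, function(x) lapply(x, function(v)
    if (is.list(v)) unlist(v) else v))
  tab <- structure(tab, class = "np_threshold_table")
  validate_threshold_table(tab)
  tab
}
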