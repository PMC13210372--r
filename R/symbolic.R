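# The 18-rule symbolic explanation engine with three-tier conflict
# resolution, plus the ventilation-flag protocol.
#
# Rule guards compare concept ACTIVATIONS (all in [0,1]) against activation
# thresholds, strictly. Threshold tokens: "tau_b" resolves to the infant's
# GA-stratified facial threshold (flat 0.7 when GA is unknown); "tau_c" and
# "tau_hr" are the flat cry (0.6) and heart-rate (0.5) defaults. The guard
# set beyond rule R1 (the published exemplar) is package configuration,
# authored to cover the four clinical categories, and fully overridable from
# a YAML rules file.

FLAT_TAUS <- c(tau_b = 0.7, tau_c = 0.6, tau_hr = 0.5)

new_rule <- function(rule_id, tier, category, guard, weight, pain_level,
                     explanation, recommendation) {
  stopifnot(tier %in% 1:3,
            category %in% c("high_confidence", "moderate", "ambiguous",
                            "no_pain"))
  if (category == "high_confidence" && tier != 1)
    np_stop("np_validation_error", "high_confidence rules must be tier 1")
  if (category == "moderate" && tier != 2)
    np_stop("np_validation_error", "moderate rules must be tier 2")
  if (category %in% c("ambiguous", "no_pain") && tier != 3)
    np_stop("np_validation_error", "%s rules must be tier 3", category)
  if (!is.na(pain_level) && !pain_level %in% 0:3)
    np_stop("np_validation_error", "pain_level must be in 0..3 or NA")
  if (weight <= 0) np_stop("np_validation_error", "rule weight must be > 0")
  list(rule_id = rule_id, tier = as.integer(tier), category = category,
       guard = guard, weight = weight, pain_level = pain_level,
       explanation = explanation, recommendation = recommendation)
}

g <- function(concept, op, threshold) {
  stopifnot(op %in% c("gt", "lt"))
  list(concept = concept, op = op, threshold = threshold)
}

#' Build the default 18-rule set
#'
#' Six high-confidence (Tier 1), five moderate (Tier 2) and seven Tier-3
#' rules (four ambiguous-conflict, three no-pain baseline). Rule R1 is the
#' canonical high-pain exemplar: brow lowering, intense crying and a heart
#' rate spike together. A dedicated 6-rule subset (`ventilated`) replaces the
#' standard set for intubated infants, using facial and physiological
#' concepts only.
#'
#' @return object of class `np_ruleset`: lists `standard` (18 rules) and
#'   `ventilated` (6 rules)
#' @export
build_default_ruleset <- function() {
  standard <- list(
    # ---- Tier 1: high-confidence pain --------------------------------------
    new_rule("R1", 1, "high_confidence",
             list(g("C1", "gt", "tau_b"), g("C5", "gt", "tau_c"),
                  g("C9", "gt", "tau_hr")),
             3.0, 3L,
             "High pain evidence: facial distress, intense crying, HR spike",
             "Immediate clinical assessment"),
    new_rule("R2", 1, "high_confidence",
             list(g("C2", "gt", "tau_b"), g("C6", "gt", 0.6),
                  g("C10", "gt", 0.5)),
             2.8, 3L,
             "High pain evidence: eye squeeze, high-pitched cry, desaturation",
             "Immediate clinical assessment"),
    new_rule("R3", 1, "high_confidence",
             list(g("C1", "gt", "tau_b"), g("C2", "gt", "tau_b"),
                  g("C3", "gt", "tau_b"), g("C4", "gt", "tau_b"),
                  g("C9", "gt", "tau_hr")),
             2.6, 3L,
             "High pain evidence: full facial response with HR acceleration",
             "Immediate clinical assessment"),
    new_rule("R4", 1, "high_confidence",
             list(g("C5", "gt", 0.8), g("C6", "gt", 0.7), g("C7", "gt", 0.5)),
             2.4, 3L,
             "High pain evidence: severe cry acoustics (intense, high-pitched, dysphonated)",
             "Immediate clinical assessment"),
    new_rule("R5", 1, "high_confidence",
             list(g("C9", "gt", 0.7), g("C10", "gt", 0.6), g("C12", "gt", 0.5)),
             2.5, 3L,
             "High pain evidence: autonomic storm (HR, desaturation, blood pressure)",
             "Immediate clinical assessment"),
    new_rule("R6", 1, "high_confidence",
             list(g("C1", "gt", "tau_b"), g("C4", "gt", "tau_b"),
                  g("C5", "gt", "tau_c"), g("C11", "gt", 0.5)),
             2.2, 3L,
             "High pain evidence: facial grimace with cry and respiratory irregularity",
             "Immediate clinical assessment"),
    # ---- Tier 2: moderate pain ---------------------------------------------
    new_rule("R7", 2, "moderate",
             list(g("C1", "gt", "tau_b"), g("C9", "gt", "tau_hr")),
             1.0, 2L,
             "Moderate pain: brow lowering with HR acceleration",
             "Comfort measures; reassess within 15 minutes"),
    new_rule("R8", 2, "moderate",
             list(g("C5", "gt", "tau_c"), g("C9", "gt", "tau_hr")),
             1.0, 2L,
             "Moderate pain: sustained crying with HR acceleration",
             "Comfort measures; reassess within 15 minutes"),
    new_rule("R9", 2, "moderate",
             list(g("C1", "gt", "tau_b"), g("C5", "gt", "tau_c")),
             1.0, 2L,
             "Moderate pain: facial distress with sustained crying",
             "Comfort measures; reassess within 15 minutes"),
    new_rule("R10", 2, "moderate",
             list(g("C2", "gt", 0.6), g("C10", "gt", 0.5)),
             1.0, 2L,
             "Moderate pain: eye squeeze with oxygen desaturation",
             "Comfort measures; check oxygen support"),
    new_rule("R11", 2, "moderate",
             list(g("C6", "gt", 0.5), g("C11", "gt", 0.5)),
             1.0, 1L,
             "Mild-to-moderate pain: pitch elevation with respiratory irregularity",
             "Non-pharmacological comfort; continue observation"),
    # ---- Tier 3: ambiguous conflict patterns -------------------------------
    new_rule("R12", 3, "ambiguous",
             list(g("C1", "gt", "tau_b"), g("C9", "lt", 0.3)),
             1.0, NA_integer_,
             "Conflicting indicators: facial distress without physiological corroboration",
             "Observe; repeat assessment"),
    new_rule("R13", 3, "ambiguous",
             list(g("C9", "gt", "tau_hr"), g("C1", "lt", 0.3),
                  g("C5", "lt", 0.3)),
             1.0, NA_integer_,
             "Conflicting indicators: HR acceleration without behavioural signs",
             "Check for non-pain causes (handling, temperature)"),
    new_rule("R14", 3, "ambiguous",
             list(g("C5", "gt", "tau_c"), g("C1", "lt", 0.3)),
             1.0, NA_integer_,
             "Conflicting indicators: crying without facial distress",
             "Assess hunger/discomfort; re-evaluate"),
    new_rule("R15", 3, "ambiguous",
             list(g("C10", "gt", 0.5), g("C9", "lt", 0.3)),
             1.0, NA_integer_,
             "Conflicting indicators: desaturation without HR response",
             "Check sensor placement and airway"),
    # ---- Tier 3: no-pain baseline ------------------------------------------
    new_rule("R16", 3, "no_pain",
             list(g("C1", "lt", 0.3), g("C5", "lt", 0.3), g("C9", "lt", 0.3)),
             1.0, 0L,
             "No pain indicators: calm face, no cry, stable heart rate",
             "Routine monitoring"),
    new_rule("R17", 3, "no_pain",
             list(g("C1", "lt", 0.2), g("C2", "lt", 0.2), g("C3", "lt", 0.2),
                  g("C4", "lt", 0.2)),
             1.0, 0L,
             "No pain indicators: relaxed facial musculature",
             "Routine monitoring"),
    new_rule("R18", 3, "no_pain",
             list(g("C5", "lt", 0.2), g("C9", "lt", 0.3), g("C10", "lt", 0.3)),
             1.0, 0L,
             "No pain indicators: quiet with stable vitals",
             "Routine monitoring")
  )
  ventilated <- list(
    new_rule("V1", 1, "high_confidence",
             list(g("C1", "gt", "tau_b"), g("C9", "gt", "tau_hr"),
                  g("C10", "gt", 0.5)),
             3.0, 3L,
             "High pain evidence (ventilated): facial distress with HR spike and desaturation",
             "Immediate clinical assessment; review analgesia"),
    new_rule("V2", 1, "high_confidence",
             list(g("C1", "gt", "tau_b"), g("C2", "gt", "tau_b"),
                  g("C9", "gt", "tau_hr")),
             2.8, 3L,
             "High pain evidence (ventilated): combined facial response with HR acceleration",
             "Immediate clinical assessment; review analgesia"),
    new_rule("V3", 1, "high_confidence",
             list(g("C9", "gt", 0.7), g("C10", "gt", 0.6), g("C12", "gt", 0.5)),
             2.5, 3L,
             "High pain evidence (ventilated): autonomic storm",
             "Immediate clinical assessment; review sedation"),
    new_rule("V4", 2, "moderate",
             list(g("C1", "gt", "tau_b"), g("C9", "gt", "tau_hr")),
             1.0, 2L,
             "Moderate pain (ventilated): brow lowering with HR acceleration",
             "Comfort measures; reassess within 15 minutes"),
    new_rule("V5", 2, "moderate",
             list(g("C2", "gt", 0.6), g("C11", "gt", 0.5)),
             1.0, 1L,
             "Mild-to-moderate pain (ventilated): eye squeeze with respiratory irregularity",
             "Non-pharmacological comfort; continue observation"),
    new_rule("V6", 2, "moderate",
             list(g("C9", "gt", 0.6), g("C10", "gt", 0.5)),
             1.0, 2L,
             "Moderate pain (ventilated): HR acceleration with desaturation",
             "Comfort measures; check ventilator synchrony")
  )
  structure(list(standard = standard, ventilated = ventilated),
            class = "np_ruleset")
}

validate_ruleset <- function(rs) {
  for (set in rs[c("standard", "ventilated")]) {
    ids <- vapply(set, function(r) r$rule_id, character(1))
    if (anyDuplicated(ids))
      np_stop("np_validation_error", "duplicate rule ids: %s",
              paste(ids[duplicated(ids)], collapse = ", "))
  }
  invisible(rs)
}

resolve_tau <- function(threshold, ga_weeks) {
  if (is.numeric(threshold)) return(threshold)
  if (threshold == "tau_b") {
    if (is.null(ga_weeks) || is.na(ga_weeks)) return(unname(FLAT_TAUS["tau_b"]))
    return(resolve_thresholds(ga_weeks = ga_weeks)$C1$activation)
  }
  if (threshold %in% names(FLAT_TAUS)) return(unname(FLAT_TAUS[threshold]))
  np_stop("np_validation_error", "unknown threshold token %s", threshold)
}

#' Evaluate the rule set against a concept vector
#'
#' A rule fires iff every guard predicate holds (strict comparison) on
#' available concepts; a guard touching an unavailable concept makes the rule
#' not fire.
#'
#' @param concepts an `np_concept_vector` (or a named numeric vector of
#'   activations, all taken as available)
#' @param context list with optional `ga_weeks` (for stratified thresholds)
#' @param ruleset a rule list (e.g. `build_default_ruleset()$standard`)
#' @return the subset of rules that fired
#' @export
evaluate_rules <- function(concepts, context = list(),
                           ruleset = build_default_ruleset()$standard) {
  if (inherits(concepts, "np_concept_vector")) {
    act <- concepts$activations
    avail <- concepts$available
  } else {
    act <- concepts
    avail <- stats::setNames(rep(TRUE, length(act)), names(act))
  }
  ga <- context$ga_weeks
  fired <- Filter(function(rule) {
    all(vapply(rule$guard, function(gd) {
      if (!isTRUE(avail[[gd$concept]])) return(FALSE)
      thr <- resolve_tau(gd$threshold, ga)
      v <- act[[gd$concept]]
      if (gd$op == "gt") v > thr else v < thr
    }, logical(1)))
  }, ruleset)
  fired
}

#' Three-tier conflict resolution
#'
#' Tier 1 firing: output of the highest-weight Tier-1 rule. Otherwise Tier 2:
#' weighted vote over fired Tier-2 rules (sum of weights per pain level,
#' argmax, ties to the higher severity). Otherwise Tier 3: the uncertainty is
#' elevated by `u_increment`; if the elevated `u` exceeds 0.5 the engine
#' abstains ("Clinician review required"), else the no-pain baseline (level
#' 0) is returned.
#'
#' @param fired_rules list of fired rules from [evaluate_rules()]
#' @param u evidential uncertainty in (0, 1\]
#' @param u_increment Tier-3 uncertainty elevation (default 0.1)
#' @return object of class `np_assessment`: `pain_level`, `abstained`,
#'   `tier`, `explanation`, `recommendation`, `fired_rule_ids`, `u_final`
#' @export
resolve_tiers <- function(fired_rules, u, u_increment = 0.1) {
  stopifnot(u > 0, u <= 1)
  ids <- vapply(fired_rules, function(r) r$rule_id, character(1))
  tiers <- vapply(fired_rules, function(r) r$tier, integer(1))
  mk <- function(pain_level, abstained, tier, explanation, recommendation,
                 u_final) {
    structure(list(pain_level = pain_level, abstained = abstained,
                   tier = tier, explanation = explanation,
                   recommendation = recommendation,
                   fired_rule_ids = ids, u_final = u_final),
              class = "np_assessment")
  }
  t1 <- fired_rules[tiers == 1L]
  if (length(t1) > 0) {
    best <- t1[[which.max(vapply(t1, function(r) r$weight, numeric(1)))]]
    return(mk(best$pain_level, FALSE, 1L, best$explanation,
              best$recommendation, u))
  }
  t2 <- fired_rules[tiers == 2L]
  if (length(t2) > 0) {
    votes <- numeric(4)
    for (r in t2) votes[r$pain_level + 1] <- votes[r$pain_level + 1] + r$weight
    lvl <- max(which(votes >= max(votes) - 1e-12)) - 1L   # ties -> severe
    winners <- Filter(function(r) r$pain_level == lvl, t2)
    best <- winners[[which.max(vapply(winners, function(r) r$weight,
                                      numeric(1)))]]
    expl <- paste(unique(vapply(t2, function(r) r$explanation, character(1))),
                  collapse = "; ")
    return(mk(lvl, FALSE, 2L, expl, best$recommendation, u))
  }
  u2 <- min(u + u_increment, 1)
  if (u2 > 0.5) {
    return(mk(NA_integer_, TRUE, 3L,
              "Conflicting or insufficient indicators; uncertainty elevated",
              "Clinician review required", u2))
  }
  t3 <- fired_rules[tiers == 3L]
  expl <- if (length(t3) > 0) {
    paste(unique(vapply(t3, function(r) r$explanation, character(1))),
          collapse = "; ")
  } else "No pain indicators above threshold"
  mk(0L, FALSE, 3L, expl, "Routine monitoring", u2)
}

#' Ventilation-flag protocol
#'
#' For ventilated infants: audio concepts C5-C8 are suppressed (marked
#' unavailable), physiological activations C9-C12 are scaled by 1.5 and
#' clamped to \[0,1\], the dedicated 6-rule ventilated subset replaces the
#' standard 18-rule set, and the uncertainty is elevated by `u_increment`.
#' Non-ventilated infants pass through unchanged.
#'
#' @param concepts an `np_concept_vector`
#' @param context list with `ventilated` (logical)
#' @param ruleset an `np_ruleset`
#' @param u_increment uncertainty elevation for ventilated cases
#' @return list: `concepts` (possibly modified), `rules` (selected rule
#'   list), `u_increment` (0 when not ventilated)
#' @export
apply_ventilation_protocol <- function(concepts, context,
                                       ruleset = build_default_ruleset(),
                                       u_increment = 0.1) {
  if (!isTRUE(context$ventilated)) {
    return(list(concepts = concepts, rules = ruleset$standard,
                u_increment = 0))
  }
  act <- concepts$activations
  avail <- concepts$available
  avail[5:8] <- FALSE
  act[9:12] <- clamp(act[9:12] * 1.5, 0, 1)
  cv <- concept_vector(act, avail, concepts$fired & avail,
                       concepts$provenance)
  list(concepts = cv, rules = ruleset$ventilated, u_increment = u_increment)
}

#' Full symbolic + evidential assessment of one episode
#'
#' Runs the rule-based detectors, applies the ventilation protocol, queries
#' the fusion model for evidential uncertainty and a neural pain prediction
#' (when a model is supplied), and resolves the symbolic tiers. The final
#' pain level is the neural prediction when a trained model is available and
#' does not abstain; otherwise the symbolic resolution stands.
#'
#' @param ep an [episode()]
#' @param model optional `np_model` / parameter list
#' @param ruleset an `np_ruleset`
#' @param tau abstention threshold
#' @param u_default uncertainty assumed when no model is supplied
#' @return an `np_assessment` with extra fields `u_model`, `neural_level`,
#'   `concepts`
#' @export
assess_episode <- function(ep, model = NULL,
                           ruleset = build_default_ruleset(), tau = 0.5,
                           u_default = 0.3) {
  cv <- suppressWarnings(detect_concepts(ep))
  vent <- apply_ventilation_protocol(
    cv, list(ventilated = ep$meta$ventilated), ruleset)
  u <- u_default
  neural <- NULL
  if (!is.null(model)) {
    fw <- fusion_forward(vent$concepts, model_params(model))
    u <- fw$ev$u
    neural <- predict_or_abstain(fw$ev, tau)
  }
  u <- min(u + vent$u_increment, 1)
  fired <- evaluate_rules(vent$concepts, list(ga_weeks = ep$meta$ga_weeks),
                          vent$rules)
  out <- resolve_tiers(fired, u)
  if (!is.null(neural) && !neural$abstain && !out$abstained) {
    out$pain_level <- neural$level
  }
  out$u_model <- u
  out$neural_level <- if (!is.null(neural)) neural$level else NA_integer_
  out$concepts <- vent$concepts
  out
}

#' Read / write a rule set as YAML
#'
#' @param rs an `np_ruleset`
#' @param path YAML file path
#' @return `path` invisibly (write) or an `np_ruleset` (read)
#' @export
write_ruleset_yaml <- function(rs, path) {
  validate_ruleset(rs)
  yaml::write_yaml(lapply(rs, function(set) lapply(set, function(r) {
    r$guard <- lapply(r$guard, function(gd) gd)
    r
  })), path)
  invisible(path)
}

#' @rdname write_ruleset_yaml
#' @export
read_ruleset_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  rs <- lapply(raw, function(set) lapply(set, function(r) {
    new_rule(r$rule_id, r$tier, r$category,
             lapply(r$guard, function(gd) g(gd$concept, gd$op, gd$threshold)),
             r$weight,
             if (is.null(r$pain_level)) NA_integer_ else as.integer(r$pain_level),
             r$explanation, r$recommendation)
  }))
  rs <- structure(rs, class = "np_ruleset")
  validate_ruleset(rs)
  rs
}
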