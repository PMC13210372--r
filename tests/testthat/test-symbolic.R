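# The 18-rule engine, three-tier resolution, ventilation protocol.

cv_from <- function(act, avail = rep(TRUE, 12)) {
  concept_vector(act, avail, rep(FALSE, 12))
}

act12 <- function(...) {
  v <- numeric(12)
  args <- list(...)
  for (nm in names(args)) v[as.integer(substring(nm, 2))] <- args[[nm]]
  stats::setNames(v, paste0("C", 1:12))
}

test_that("default rule set has the published structure", {
  rs <- build_default_ruleset()
  expect_length(rs$standard, 18)
  tiers <- vapply(rs$standard, function(r) r$tier, integer(1))
  expect_identical(as.integer(table(tiers)), c(6L, 5L, 7L))
  cats <- vapply(rs$standard, function(r) r$category, character(1))
  expect_identical(sum(cats == "high_confidence"), 6L)
  expect_identical(sum(cats == "moderate"), 5L)
  expect_identical(sum(cats == "ambiguous"), 4L)
  expect_identical(sum(cats == "no_pain"), 3L)
  expect_length(rs$ventilated, 6)
  r1 <- rs$standard[[1]]
  expect_identical(r1$rule_id, "R1")
  expect_identical(vapply(r1$guard, function(g) g$concept, character(1)),
                   c("C1", "C5", "C9"))
  expect_identical(vapply(r1$guard, function(g) g$threshold, character(1)),
                   c("tau_b", "tau_c", "tau_hr"))
})

test_that("R1 reproduces the canonical explanation and recommendation", {
  # activations (brow, cry, hr) = (0.8, 0.7, 0.6) against (0.7, 0.6, 0.5)
  cv <- cv_from(act12(C1 = 0.8, C5 = 0.7, C9 = 0.6))
  fired <- evaluate_rules(cv, list(), build_default_ruleset()$standard)
  ids <- vapply(fired, function(r) r$rule_id, character(1))
  expect_true("R1" %in% ids)
  a <- resolve_tiers(fired, u = 0.2)
  expect_identical(a$tier, 1L)
  expect_identical(a$explanation,
                   "High pain evidence: facial distress, intense crying, HR spike")
  expect_identical(a$recommendation, "Immediate clinical assessment")
})

test_that("guards are strict and GA-stratified", {
  rs <- build_default_ruleset()$standard
  # exactly at tau_b = 0.7: R1 must NOT fire
  cv <- cv_from(act12(C1 = 0.7, C5 = 0.7, C9 = 0.6))
  ids <- vapply(evaluate_rules(cv, list(), rs), function(r) r$rule_id,
                character(1))
  expect_false("R1" %in% ids)
  # extremely preterm: stratified tau_b = 0.60 admits brow = 0.65
  cv <- cv_from(act12(C1 = 0.65, C5 = 0.7, C9 = 0.6))
  ids <- vapply(evaluate_rules(cv, list(ga_weeks = 26), rs),
                function(r) r$rule_id, character(1))
  expect_true("R1" %in% ids)
  ids_term <- vapply(evaluate_rules(cv, list(ga_weeks = 39), rs),
                     function(r) r$rule_id, character(1))
  expect_false("R1" %in% ids_term)
})

test_that("guards touching unavailable concepts never fire", {
  avail <- rep(TRUE, 12)
  avail[5] <- FALSE
  cv <- cv_from(act12(C1 = 0.9, C5 = 0.9, C9 = 0.9), avail)
  ids <- vapply(evaluate_rules(cv, list(), build_default_ruleset()$standard),
                function(r) r$rule_id, character(1))
  expect_false("R1" %in% ids)   # C5 unavailable blocks R1
  expect_true("R7" %in% ids)    # C1 + C9 rule unaffected
})

test_that("tier-2 weighted voting picks the heavier level, ties to severity", {
  w2 <- function(id, lvl, wt) neopain:::new_rule(
    id, 2L, "moderate", list(neopain:::g("C1", "gt", 0)), wt, lvl, "m", "r")
  fired <- list(w2("A", 2L, 2.0), w2("B", 1L, 1.0))
  a <- resolve_tiers(fired, 0.2)
  expect_identical(a$tier, 2L)
  expect_identical(a$pain_level, 2L)
  tie <- list(w2("A", 1L, 1.5), w2("B", 2L, 1.5))
  expect_identical(resolve_tiers(tie, 0.2)$pain_level, 2L)
})

test_that("tier 3 elevates u and abstains past 0.5", {
  a <- resolve_tiers(list(), u = 0.45)
  expect_true(a$abstained)
  expect_identical(a$recommendation, "Clinician review required")
  expect_equal(a$u_final, 0.55)
  expect_true(is.na(a$pain_level))
  b <- resolve_tiers(list(), u = 0.2)
  expect_false(b$abstained)
  expect_identical(b$pain_level, 0L)
  expect_identical(b$tier, 3L)
  expect_equal(b$u_final, 0.3)
})

test_that("tier-1 output is invariant to modifying lower tiers", {
  set.seed(123)
  rs <- build_default_ruleset()
  for (i in 1:1000) {
    act <- stats::runif(12)
    act[1] <- stats::runif(1, 0.76, 1)   # force R1's guards
    act[5] <- stats::runif(1, 0.61, 1)
    act[9] <- stats::runif(1, 0.51, 1)
    cv <- cv_from(act)
    u <- stats::runif(1, 0.05, 1)
    full <- resolve_tiers(evaluate_rules(cv, list(), rs$standard), u)
    t1_only <- Filter(function(r) r$tier == 1L, rs$standard)
    pruned <- resolve_tiers(evaluate_rules(cv, list(), t1_only), u)
    expect_identical(full$pain_level, pruned$pain_level)
    expect_identical(full$tier, 1L)
    expect_identical(full$explanation, pruned$explanation)
  }
})

test_that("the engine is total and deterministic", {
  set.seed(321)
  rs <- build_default_ruleset()$standard
  for (i in 1:200) {
    avail <- stats::runif(12) > 0.2
    if (!any(avail)) avail[1] <- TRUE
    cv <- cv_from(stats::runif(12) * avail, avail)
    u <- stats::runif(1, 0.01, 1)
    a1 <- resolve_tiers(evaluate_rules(cv, list(), rs), u)
    a2 <- resolve_tiers(evaluate_rules(cv, list(), rs), u)
    expect_s3_class(a1, "np_assessment")
    expect_identical(xor(is.na(a1$pain_level), !a1$abstained), TRUE)
    expect_identical(a1$explanation, a2$explanation)
    expect_identical(a1$u_final, a2$u_final)
  }
})

test_that("ventilation protocol suppresses audio and boosts physio", {
  cv <- cv_from(act12(C5 = 0.9, C9 = 0.8, C10 = 0.4))
  out <- apply_ventilation_protocol(cv, list(ventilated = TRUE))
  expect_false(any(out$concepts$available[5:8]))
  expect_equal(unname(out$concepts$activations["C9"]), 1.0)  # 0.8*1.5 clamped
  expect_equal(unname(out$concepts$activations["C10"]), 0.6)
  expect_length(out$rules, 6)
  expect_equal(out$u_increment, 0.1)
  same <- apply_ventilation_protocol(cv, list(ventilated = FALSE))
  expect_identical(same$concepts$activations, cv$activations)
  expect_length(same$rules, 18)
  expect_equal(same$u_increment, 0)
})

test_that("the shipped YAML configuration matches the in-code defaults", {
  thr_path <- system.file("extdata", "thresholds.yaml", package = "neopain")
  rules_path <- system.file("extdata", "rules.yaml", package = "neopain")
  expect_true(nzchar(thr_path) && nzchar(rules_path))
  tab <- read_thresholds_yaml(thr_path)
  expect_equal(tab$C1$strata, default_thresholds()$C1$strata)
  expect_equal(tab$C9$abs_bpm, 180)
  rs <- read_ruleset_yaml(rules_path)
  expect_length(rs$standard, 18)
  expect_length(rs$ventilated, 6)
  expect_identical(rs$standard[[1]]$explanation,
                   build_default_ruleset()$standard[[1]]$explanation)
})

test_that("rule sets round-trip through YAML and reject duplicates", {
  rs <- build_default_ruleset()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_ruleset_yaml(rs, path)
  back <- read_ruleset_yaml(path)
  expect_length(back$standard, 18)
  expect_identical(back$standard[[1]]$explanation, rs$standard[[1]]$explanation)
  raw <- yaml::read_yaml(path)
  raw$standard[[2]]$rule_id <- "R1"
  path2 <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(raw, path2)
  expect_np_error(read_ruleset_yaml(path2), "np_validation_error")
  raw2 <- yaml::read_yaml(path)
  raw2$standard[[1]]$tier <- 3L
  yaml::write_yaml(raw2, path2)
  expect_np_error(read_ruleset_yaml(path2), "np_validation_error")
})
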