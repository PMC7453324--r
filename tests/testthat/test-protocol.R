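test_that("schedule instantiation creates visits in order and matches the matrix cell-by-cell", {
  fx <- getFixture("mumbai-like")
  defn <- fx$definition
  rig <- rigStore(defn)
  registerDevice(rig$store, "01")
  pid <- registerParticipant(rig$store, defn, rig$ra, dobExact(Sys.Date() - 450))
  keys <- instantiateSchedule(rig$store, defn, rig$ra, pid)
  # 3 consent visits (prescreening, screening, enrollment) + 9 monthly follow-ups
  expect_length(keys, 12)
  expect_identical(keys,
                   paste(pid, unlist(defn$visit_order), sep = "|"))

  # oracle: iterate the raw schedule; every always-mode cell (consent cells
  # restricted to the routed band) must have exactly one instance, and no
  # midline/trigger cell any
  routed <- requiredConsentForms(rig$store, defn, pid)
  for (cell in defn$schedule) {
    insts <- crfInstancesFor(rig$store, pid, cell$visit_id, cell$crf_id)
    consent <- isTRUE(defn$crfs[[cell$crf_id]]$is_consent_form)
    expected <- if (cell$mode == "always" && (!consent || cell$crf_id %in% routed)) 1L else 0L
    expect_length(insts, expected)
  }
  expect_error(instantiateSchedule(rig$store, defn, rig$ra, pid),
               class = "edc_state_error")
})

test_that("a definition with zero scheduled visits instantiates nothing", {
  defn <- miniStudy(crf_ids = "a", scheduled = FALSE)
  rig <- rigStore(defn)
  pid <- registerParticipant(rig$store, defn, rig$ra, dobExact("1990-01-01"))
  expect_length(instantiateSchedule(rig$store, defn, rig$ra, pid), 0)
})

surveilRig <- function(age_years = 30) {
  fx <- getFixture("surveillance-like")
  rig <- rigStore(fx$definition)
  p <- surveilParticipant(rig, fx, age_years = age_years)
  c(rig, p, list(defn = fx$definition))
}

test_that("value entry enforces ranges: warn pends on acknowledgment, block rejects", {
  r <- surveilRig()
  instantiateSchedule(r$store, r$defn, r$ra, r$pid)
  key <- paste(r$pid, "health_visit", "anthropometry", 1, sep = "|")

  res <- enterValue(r$store, r$defn, r$ra, key, "weight_kg", 1)
  expect_false(res$stored)
  expect_identical(res$flags[[1]]$severity, "warn")
  expect_true(is.null(r$store$state$crfs[[key]]$values$weight_kg))

  res2 <- enterValue(r$store, r$defn, r$ra, key, "weight_kg", 1, acknowledge = TRUE)
  expect_true(res2$stored)
  expect_identical(r$store$state$crfs[[key]]$values$weight_kg, 1)
  expect_length(pendingFlags(r$store, key), 0)  # acknowledged on entry

  res3 <- enterValue(r$store, r$defn, r$ra, key, "weight_kg", -3)
  expect_false(res3$stored)
  expect_identical(res3$flags[[1]]$severity, "block")
  expect_identical(r$store$state$crfs[[key]]$values$weight_kg, 1)

  res4 <- enterValue(r$store, r$defn, r$ra, key, "weight_kg", 60)
  expect_true(res4$stored)
  expect_length(res4$flags, 0)
})

test_that("entry errors: hidden variables, type mismatches, signed instances", {
  r <- surveilRig()
  instantiateSchedule(r$store, r$defn, r$ra, r$pid)
  key <- paste(r$pid, "health_visit", "anthropometry", 1, sep = "|")
  expect_error(enterValue(r$store, r$defn, r$ra, key, "height_r2", 150),
               class = "edc_visibility_error")
  expect_error(enterValue(r$store, r$defn, r$ra, key, "weight_kg", "heavy"),
               class = "edc_type_error")
  expect_error(enterValue(r$store, r$defn, r$ra, key, "dominant_arm", "up"),
               class = "edc_type_error")

  skey <- paste(r$pid, "screening_visit", "screening", 1, sep = "|")
  fillAndComplete(r$store, r$defn, r$ra, skey,
                  list(pregnant = "0", lactating = "0"),
                  sign_as = list(list(username = "ra", password = "ra-pw")))
  expect_error(enterValue(r$store, r$defn, r$ra, skey, "pregnant", "1"),
               class = "edc_permission_error")
})

test_that("completion requires required values and acknowledged flags", {
  r <- surveilRig()
  instantiateSchedule(r$store, r$defn, r$ra, r$pid)
  key <- paste(r$pid, "health_visit", "health_questionnaire", 1, sep = "|")
  expect_error(completeCrf(r$store, r$defn, r$ra, key),
               class = "edc_completeness_error")

  enterValue(r$store, r$defn, r$ra, key, "ever_pregnant", "0")
  enterValue(r$store, r$defn, r$ra, key, "pregnancies_count", 2)
  # contradiction: completion refused until the cross-field flag is acknowledged
  expect_error(completeCrf(r$store, r$defn, r$ra, key),
               class = "edc_flag_error")
  for (fid in names(pendingFlags(r$store, key))) {
    acknowledgeFlag(r$store, r$ra, key, fid)
  }
  completeCrf(r$store, r$defn, r$ra, key)
  expect_identical(r$store$state$crfs[[key]]$status, "complete")
  expect_false(is.null(r$store$state$crfs[[key]]$completed_at))
})

test_that("count triggers spawn, reconcile upward and never delete data", {
  r <- surveilRig()
  instantiateSchedule(r$store, r$defn, r$ra, r$pid)
  key <- paste(r$pid, "health_visit", "health_questionnaire", 1, sep = "|")
  enterValue(r$store, r$defn, r$ra, key, "ever_pregnant", "1")
  enterValue(r$store, r$defn, r$ra, key, "pregnancies_count", 2)
  completeCrf(r$store, r$defn, r$ra, key)
  preg <- crfInstancesFor(r$store, r$pid, "health_visit", "pregnancy")
  expect_length(preg, 2)

  # enter data into the first spawned instance, then grow the count to 3
  k1 <- names(preg)[[1]]
  enterValue(r$store, r$defn, r$ra, k1, "outcome", "1")
  enterValue(r$store, r$defn, r$ra, key, "pregnancies_count", 3)
  completeCrf(r$store, r$defn, r$ra, key)
  preg3 <- crfInstancesFor(r$store, r$pid, "health_visit", "pregnancy")
  expect_length(preg3, 3)
  expect_identical(unname(sort(vapply(preg3, function(i) i$origin$rule_ordinal,
                                      integer(1)))), 1:3)
  expect_identical(r$store$state$crfs[[k1]]$values$outcome, "1")

  # idempotent on unchanged value
  completeCrf(r$store, r$defn, r$ra, key)
  expect_length(crfInstancesFor(r$store, r$pid, "health_visit", "pregnancy"), 3)

  # shrink retires (never deletes) and flags the instance holding data
  enterValue(r$store, r$defn, r$ra, key, "pregnancies_count", 0)
  completeCrf(r$store, r$defn, r$ra, key)
  expect_length(crfInstancesFor(r$store, r$pid, "health_visit", "pregnancy"), 0)
  all_insts <- crfInstancesFor(r$store, r$pid, "health_visit", "pregnancy",
                               include_surplus = TRUE)
  expect_length(all_insts, 3)
  flagged <- Filter(function(i) length(i$flags) > 0, all_insts)
  expect_identical(names(flagged), k1)
})

test_that("predicate triggers spawn one specimen CRF on a positive sick form", {
  fx <- getFixture("mumbai-like")
  defn <- fx$definition
  rig <- rigStore(defn)
  registerDevice(rig$store, "01")
  pid <- registerParticipant(rig$store, defn, rig$ra, dobExact(Sys.Date() - 450))
  instantiateSchedule(rig$store, defn, rig$ra, pid)
  key <- paste(pid, "fu1", "followup_health", 1, sep = "|")
  enterValue(rig$store, defn, rig$ra, key, "illness_today", "1")
  enterValue(rig$store, defn, rig$ra, key, "fever", "1")
  spawned <- completeCrf(rig$store, defn, rig$ra, key)
  expect_length(spawned, 1)
  expect_length(crfInstancesFor(rig$store, pid, "fu1", "sick_specimen"), 1)

  key2 <- paste(pid, "fu2", "followup_health", 1, sep = "|")
  enterValue(rig$store, defn, rig$ra, key2, "illness_today", "0")
  enterValue(rig$store, defn, rig$ra, key2, "fever", "0")
  expect_length(completeCrf(rig$store, defn, rig$ra, key2), 0)
  expect_length(crfInstancesFor(rig$store, pid, "fu2", "sick_specimen"), 0)
})

test_that("consent routing follows the half-open age bands to the day", {
  fx <- getFixture("surveillance-like")
  rig <- rigStore(fx$definition)
  mk <- function(age) {
    registerParticipant(rig$store, fx$definition, rig$ra,
                        dobExact(Sys.Date() - round(age * 365.25) - 10))
  }
  p17 <- mk(17); p18 <- mk(18)
  expect_setequal(requiredConsentForms(rig$store, fx$definition, p17),
                  c("assent_adolescent", "consent_parental"))
  expect_identical(requiredConsentForms(rig$store, fx$definition, p18),
                   "consent_adult")
  # an ambiguous 17/18-year-old (partial date) resolves to the minor band
  pid <- registerParticipant(rig$store, fx$definition, rig$ra,
                             dobPartial(as.integer(format(Sys.Date(), "%Y")) - 18))
  expect_setequal(requiredConsentForms(rig$store, fx$definition, pid),
                  c("assent_adolescent", "consent_parental"))
})

test_that("a 14-year-old is excluded by eligibility before consent is ever requested", {
  fx <- getFixture("surveillance-like")
  rig <- rigStore(fx$definition)
  pid <- registerParticipant(rig$store, fx$definition, rig$ra,
                             dobExact(Sys.Date() - round(14 * 365.25)))
  expect_identical(rig$store$state$eligibility[[pid]]$overall, "ineligible")
  instantiateSchedule(rig$store, fx$definition, rig$ra, pid)
  permitted <- gateProgression(rig$store, fx$definition, pid)
  expect_false(any(c("assent_adolescent", "consent_parental", "consent_adult")
                   %in% permitted))
})

test_that("progression gating opens CRFs only as prerequisites are met", {
  r <- surveilRig(age_years = 30)
  instantiateSchedule(r$store, r$defn, r$ra, r$pid)

  # before consent: only pre-consent CRFs and the routed adult consent form
  expect_setequal(gateProgression(r$store, r$defn, r$pid),
                  c("consent_adult", "household_form", "recruitment", "screening"))

  # screening passes, consent signed -> the visit-2 CRFs open once visit 1 completes
  sk <- paste(r$pid, "screening_visit", "screening", 1, sep = "|")
  fillAndComplete(r$store, r$defn, r$ra, sk,
                  list(pregnant = "0", lactating = "0"),
                  sign_as = list(list(username = "ra", password = "ra-pw")))
  for (crf in c("household_form", "recruitment", "consent_adult")) {
    key <- paste(r$pid, "screening_visit", crf, 1, sep = "|")
    vals <- switch(crf,
                   household_form = list(n_members = 4, water_source = "1"),
                   recruitment = list(name_full = "Test Person"),
                   consent_adult = list(consent_given = "1",
                                        participant_signature = "ref:sig"))
    fillAndComplete(r$store, r$defn, r$ra, key, vals,
                    sign_as = list(list(username = "ra", password = "ra-pw")))
  }
  expect_identical(visitStatus(r$store, r$defn, r$pid, "screening_visit"),
                   "complete")
  permitted <- gateProgression(r$store, r$defn, r$pid)
  expect_true(all(c("health_questionnaire", "anthropometry") %in% permitted))
})

test_that("multi-slot signatures demand distinct verified personnel", {
  fx <- getFixture("feverphone-like")
  defn <- fx$definition
  rig <- rigStore(defn)
  pid <- registerParticipant(rig$store, defn, rig$ra, dobExact("1990-04-01"))
  instantiateSchedule(rig$store, defn, rig$ra, pid)
  key <- paste(pid, "enrollment", "clinical_signs", 1, sep = "|")

  expect_error(signCrf(rig$store, defn, key, "ra", "ra-pw"),
               class = "edc_state_error")  # not complete yet

  fillAndComplete(rig$store, defn, rig$ra, key,
                  list(temperature_c = 38.5, fever_days = 2, severe = "0"))
  expect_error(signCrf(rig$store, defn, key, "ra", "wrong"),
               class = "edc_auth_error")
  expect_identical(signCrf(rig$store, defn, key, "ra", "ra-pw"), "complete")
  expect_error(signCrf(rig$store, defn, key, "ra", "ra-pw"),
               class = "edc_state_error")  # same person, second slot
  expect_identical(signCrf(rig$store, defn, key, "ra2", "ra-pw"), "signed")
  expect_true(all(vapply(rig$store$state$crfs[[key]]$signatures,
                         function(s) isTRUE(s$credential_verified), logical(1))))
})

test_that("incremental visit status equals from-scratch recomputation after any event sequence", {
  r <- surveilRig()
  instantiateSchedule(r$store, r$defn, r$ra, r$pid)
  checkAll <- function() {
    for (vid in unlist(r$defn$visit_order)) {
      vk <- paste(r$pid, vid, sep = "|")
      expect_identical(r$store$state$visits[[vk]]$status,
                       visitStatus(r$store, r$defn, r$pid, vid))
    }
  }
  checkAll()
  sk <- paste(r$pid, "screening_visit", "screening", 1, sep = "|")
  enterValue(r$store, r$defn, r$ra, sk, "pregnant", "0"); checkAll()
  enterValue(r$store, r$defn, r$ra, sk, "lactating", "0"); checkAll()
  completeCrf(r$store, r$defn, r$ra, sk); checkAll()
  signCrf(r$store, r$defn, sk, "ra", "ra-pw"); checkAll()
})

test_that("every instance maps to a schedule cell, a midline designation, or a live trigger", {
  fx <- getFixture("mumbai-like")
  sim <- simulateSessions(fx, n_participants = 4, n_devices = 2, seed = 3,
                          error_rate = 0)
  defn <- fx$definition
  cells <- vapply(defn$schedule, function(c) paste(c$visit_id, c$crf_id),
                  character(1))
  for (inst in sim$server$state$crfs) {
    origin <- inst$origin$kind
    if (origin == "scheduled") {
      expect_true(paste(inst$visit_id, inst$crf_id) %in% cells ||
                    inst$visit_id == "unscheduled")
    } else if (origin == "midline-designated") {
      alloc <- sim$server$state$allocations[[inst$participant]]
      expect_identical(inst$visit_id, alloc$midline_visit)
    } else {
      expect_identical(origin, "triggered")
      expect_true(inst$origin$rule_id %in% names(defn$triggers))
    }
  }
})

test_that("the audited edit path voids signatures and can flip eligibility", {
  fx <- getFixture("mumbai-like")
  defn <- fx$definition
  rig <- rigStore(defn)
  registerDevice(rig$store, "01")
  pid <- registerParticipant(rig$store, defn, rig$ra, dobExact(Sys.Date() - 450))
  instantiateSchedule(rig$store, defn, rig$ra, pid)
  ak <- paste(pid, "screening", "anthro_screen", 1, sep = "|")
  fillAndComplete(rig$store, defn, rig$ra, ak,
                  list(age_months = 30, weight_kg = 10),
                  sign_as = list(list(username = "ra", password = "ra-pw")))
  expect_identical(rig$store$state$eligibility[[pid]]$overall, "ineligible")

  expect_error(editSignedValue(rig$store, defn, rig$ra, ak, "age_months", 15),
               class = "edc_permission_error")
  editSignedValue(rig$store, defn, rig$dm, ak, "age_months", 15)
  inst <- rig$store$state$crfs[[ak]]
  expect_identical(inst$status, "complete")
  expect_length(inst$signatures, 0)
  # terminal exclusion flipped back to pending by the audited correction
  expect_identical(rig$store$state$eligibility[[pid]]$overall, "pending")
  hist <- auditHistory(rig$store, "crfs", ak)
  edits <- Filter(function(h) isTRUE(h$meta$edit_signed), hist)
  expect_gte(length(edits), 2)
})
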