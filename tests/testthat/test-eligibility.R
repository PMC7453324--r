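completeScreening <- function(rig, defn, pid, pregnant = "0", lactating = "0") {
  sk <- paste(pid, "screening_visit", "screening", 1, sep = "|")
  fillAndComplete(rig$store, defn, rig$ra, sk,
                  list(pregnant = pregnant, lactating = lactating))
  sk
}

test_that("a woman aged 30, not pregnant, not lactating, is eligible once predicates complete", {
  fx <- getFixture("surveillance-like")
  rig <- rigStore(fx$definition)
  p <- surveilParticipant(rig, fx, age_years = 30)
  instantiateSchedule(rig$store, fx$definition, rig$ra, p$pid)
  expect_identical(rig$store$state$eligibility[[p$pid]]$overall, "pending")
  completeScreening(rig, fx$definition, p$pid)
  st <- rig$store$state$eligibility[[p$pid]]
  expect_identical(st$overall, "eligible")
  expect_true(all(unlist(st$per_criterion) == "pass"))
  expect_identical(rig$store$state$participants[[p$pid]]$status, "eligible")
})

test_that("a single negative criterion excludes immediately, other CRFs still pending", {
  fx <- getFixture("surveillance-like")
  rig <- rigStore(fx$definition)
  # age 45 outside [15, 40]: ineligible at registration, nothing completed yet
  pid <- registerParticipant(rig$store, fx$definition, rig$ra,
                             dobExact(Sys.Date() - round(45.5 * 365.25)))
  st <- rig$store$state$eligibility[[pid]]
  expect_identical(st$overall, "ineligible")
  expect_identical(st$per_criterion$reproductive_age, "fail")
  expect_identical(st$per_criterion$not_pregnant, "pending")

  # pregnant at screening: exclusion via a CRF-backed criterion
  p2 <- surveilParticipant(rig, fx, age_years = 25)
  instantiateSchedule(rig$store, fx$definition, rig$ra, p2$pid)
  completeScreening(rig, fx$definition, p2$pid, pregnant = "1")
  expect_identical(rig$store$state$eligibility[[p2$pid]]$overall, "ineligible")
})

test_that("exclusion short-circuits before all predicate CRFs are complete", {
  fx <- getFixture("mumbai-like")
  rig <- rigStore(fx$definition)
  registerDevice(rig$store, "01")
  pid <- registerParticipant(rig$store, fx$definition, rig$ra,
                             dobExact(Sys.Date() - 450))
  instantiateSchedule(rig$store, fx$definition, rig$ra, pid)
  ak <- paste(pid, "screening", "anthro_screen", 1, sep = "|")
  fillAndComplete(rig$store, fx$definition, rig$ra, ak,
                  list(age_months = 30, weight_kg = 10))
  st <- rig$store$state$eligibility[[pid]]
  expect_identical(st$overall, "ineligible")  # lab_screen still incomplete
  expect_identical(st$per_criterion$not_severely_anemic, "pending")
})

test_that("final state is order-independent across completion permutations", {
  defn <- miniStudy(crf_ids = c("a", "b", "c"),
                    criteria = c(k1 = "a.x > 0",
                                 k2 = "b.x > 0 & c.x < 10",
                                 k3 = "a.x + c.x >= 2"))
  set.seed(99)
  for (rep in seq_len(200)) {
    vals <- list(a = sample(-1:3, 1), b = sample(-1:3, 1), c = sample(0:12, 1))
    states <- vapply(seq_len(2), function(j) {
      rig <- rigStore(defn, device = sprintf("%02d", j))
      pid <- registerParticipant(rig$store, defn, rig$ra, dobExact("1990-01-01"))
      instantiateSchedule(rig$store, defn, rig$ra, pid)
      for (cid in sample(c("a", "b", "c"))) {
        key <- paste(pid, "v1", cid, 1, sep = "|")
        enterValue(rig$store, defn, rig$ra, key, "x", vals[[cid]])
        completeCrf(rig$store, defn, rig$ra, key)
      }
      rig$store$state$eligibility[[pid]]$overall
    }, character(1))
    expect_identical(states[[1]], states[[2]])

    # brute-force oracle on the full record
    oracle <- if (vals$a > 0 && (vals$b > 0 && vals$c < 10) &&
                  (vals$a + vals$c >= 2)) "eligible" else "ineligible"
    expect_identical(states[[1]], oracle)
  }
})

test_that("exclusion is monotone: later completions never readmit", {
  defn <- miniStudy(crf_ids = c("a", "b"),
                    criteria = c(k1 = "a.x > 0", k2 = "b.x > 0"))
  rig <- rigStore(defn)
  pid <- registerParticipant(rig$store, defn, rig$ra, dobExact("1990-01-01"))
  instantiateSchedule(rig$store, defn, rig$ra, pid)
  ka <- paste(pid, "v1", "a", 1, sep = "|")
  kb <- paste(pid, "v1", "b", 1, sep = "|")
  enterValue(rig$store, defn, rig$ra, ka, "x", -5)
  completeCrf(rig$store, defn, rig$ra, ka)
  expect_identical(rig$store$state$eligibility[[pid]]$overall, "ineligible")
  enterValue(rig$store, defn, rig$ra, kb, "x", 7)
  completeCrf(rig$store, defn, rig$ra, kb)
  expect_identical(rig$store$state$eligibility[[pid]]$overall, "ineligible")
})

test_that("zero criteria yield eligibility on the empty predicate set", {
  defn <- miniStudy(crf_ids = "a")
  rig <- rigStore(defn)
  pid <- registerParticipant(rig$store, defn, rig$ra, dobExact("1990-01-01"))
  expect_identical(evaluateEligibility(rig$store, defn, pid)$overall, "eligible")
})

test_that("the eligibility report names pending predicate CRFs and failing criteria", {
  fx <- getFixture("surveillance-like")
  rig <- rigStore(fx$definition)
  p <- surveilParticipant(rig, fx, age_years = 30)
  instantiateSchedule(rig$store, fx$definition, rig$ra, p$pid)
  rep1 <- eligibilityReport(rig$store, fx$definition, p$pid)
  expect_identical(attr(rep1, "overall"), "pending")
  expect_identical(rep1$missing_crfs[rep1$criterion_id == "not_pregnant"],
                   "screening")

  # one constructed failure per criterion: the report identifies exactly it
  cases <- list(list(pregnant = "1", lactating = "0", fail = "not_pregnant"),
                list(pregnant = "0", lactating = "1", fail = "not_lactating"))
  for (cs in cases) {
    p2 <- surveilParticipant(rig, fx, age_years = 30)
    instantiateSchedule(rig$store, fx$definition, rig$ra, p2$pid)
    completeScreening(rig, fx$definition, p2$pid, cs$pregnant, cs$lactating)
    rep2 <- eligibilityReport(rig$store, fx$definition, p2$pid)
    expect_identical(rep2$criterion_id[rep2$status == "fail"], cs$fail)
    # reporting never mutates state
    before <- rig$store$counter
    eligibilityReport(rig$store, fx$definition, p2$pid)
    expect_identical(rig$store$counter, before)
  }
})
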