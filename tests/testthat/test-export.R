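test_that("export writes one file per CRF type plus registry tables, byte-stably", {
  fx <- getFixture("mumbai-like")
  sim <- simulateSessions(fx, n_participants = 5, n_devices = 1, seed = 13,
                          error_rate = 0)
  defn <- fx$definition
  dm <- authenticate(sim$server, "dm1", "dm-pass")

  d1 <- tempfile(); files <- exportTables(sim$server, defn, dm, d1)
  crf_files <- setdiff(names(files),
                       c("participants", "households", "allocations"))
  expect_setequal(crf_files, names(defn$crfs))

  d2 <- tempfile(); files2 <- exportTables(sim$server, defn, dm, d2)
  for (nm in names(files)) {
    expect_identical(readLines(files[[nm]]), readLines(files2[[nm]]),
                     label = nm)
  }

  # export is role-gated; a research assistant is denied
  ra <- authenticate(sim$server, "ra01a", "ra-pass")
  expect_error(exportTables(sim$server, defn, ra, tempfile()),
               class = "edc_permission_error")
  expect_error(exportTables(sim$server, defn, dm, tempfile(),
                            crfs = "no_such_crf"),
               class = "edc_reference_error")
})

test_that("deidentified exports contain no identifying column anywhere", {
  fx <- getFixture("surveillance-like")
  sim <- simulateSessions(fx, n_participants = 5, n_devices = 2, seed = 17,
                          error_rate = 0)
  defn <- fx$definition
  dm <- authenticate(sim$server, "dm1", "dm-pass")
  dir <- tempfile()
  files <- exportTables(sim$server, defn, dm, dir, deidentify = TRUE)

  identifying <- unlist(lapply(names(defn$crfs), function(cid) {
    names(Filter(function(v) isTRUE(v$identifying),
                 defn$crfs[[cid]]$variables))
  }))
  identifying <- unique(c(identifying, "name_full"))
  for (f in files) {
    hdr <- names(utils::read.csv(f, nrows = 1, check.names = FALSE))
    expect_length(intersect(hdr, identifying), 0)
  }
  # the identified export does carry them, as a control
  files_id <- exportTables(sim$server, defn, dm, tempfile())
  hdr <- names(utils::read.csv(files_id[["recruitment"]], nrows = 1,
                               check.names = FALSE))
  expect_true("name_full" %in% hdr)
})

test_that("triggered instances export with ordinals that support downstream merges", {
  fx <- getFixture("surveillance-like")
  defn <- fx$definition
  rig <- rigStore(defn)
  counts <- c(2L, 3L)
  pids <- character(0)
  for (n in counts) {
    p <- surveilParticipant(rig, fx, age_years = 30)
    instantiateSchedule(rig$store, defn, rig$ra, p$pid)
    key <- paste(p$pid, "health_visit", "health_questionnaire", 1, sep = "|")
    fillAndComplete(rig$store, defn, rig$ra, key,
                    list(ever_pregnant = "1", pregnancies_count = n))
    pids <- c(pids, p$pid)
  }
  dir <- tempfile()
  files <- exportTables(rig$store, defn, rig$dm, dir)
  preg <- utils::read.csv(files[["pregnancy"]], check.names = FALSE)
  # merge oracle: joining on (personal_id, visit, ordinal) recovers n per participant
  recovered <- vapply(pids, function(pid) {
    rows <- preg[preg$personal_id == pid, ]
    expect_setequal(rows$ordinal, seq_len(nrow(rows)))
    nrow(rows)
  }, integer(1))
  expect_identical(unname(recovered), as.integer(counts))
})

test_that("choice variables export code plus language-resolved label columns", {
  fx <- getFixture("surveillance-like")
  defn <- fx$definition
  rig <- rigStore(defn)
  p <- surveilParticipant(rig, fx)
  instantiateSchedule(rig$store, defn, rig$ra, p$pid)
  key <- paste(p$pid, "screening_visit", "screening", 1, sep = "|")
  enterValue(rig$store, defn, rig$ra, key, "pregnant", "0")
  files <- exportTables(rig$store, defn, rig$dm, tempfile())
  scr <- utils::read.csv(files[["screening"]], check.names = FALSE,
                         colClasses = "character")
  row <- scr[scr$personal_id == p$pid, ]
  expect_identical(row$pregnant, "0")
  expect_identical(row$pregnant_label, "No")
})

makeLabFile <- function(pids, values) {
  data.frame(personal_id = pids, hb_gdl = values, stringsAsFactors = FALSE)
}

test_that("external results import through the normal validation path", {
  fx <- getFixture("mumbai-like")
  defn <- fx$definition
  rig <- rigStore(defn)
  registerDevice(rig$store, "01")
  pids <- vapply(1:10, function(i)
    registerParticipant(rig$store, defn, rig$ra, dobExact(Sys.Date() - 450)),
    character(1))

  rep <- importExternalResults(rig$store, defn, rig$ra,
                               makeLabFile(pids, rep(11, 10)), "lab_screen")
  expect_identical(nrow(rep), 10L)
  expect_true(all(rep$accepted))
  expect_true(all(rep$status == "complete"))

  # one unknown id among ten: rejected and reported, others imported
  rep2 <- importExternalResults(rig$store, defn, rig$ra,
                                makeLabFile(c(pids[1:9], "XXXX"), rep(11, 10)),
                                "lab_screen")
  expect_identical(sum(rep2$accepted), 9L)
  expect_match(rep2$reason[!rep2$accepted], "unknown participant")

  # out-of-range value: stored with its warn flag pending, like interactive entry
  rep3 <- importExternalResults(rig$store, defn, rig$ra,
                                makeLabFile(pids[1], 22), "lab_screen")
  expect_identical(rep3$status, "in-progress")
  key <- rep3$instance_key
  expect_identical(rig$store$state$crfs[[key]]$values$hb_gdl, 22)
  pend <- pendingFlags(rig$store, key)
  expect_length(pend, 1)
  # same-flags oracle: interactive entry of the identical value raises the
  # same flag multiset
  ikey <- edcflow:::createCrfInstance(rig$store, defn, pids[2], "unscheduled",
                                      "lab_screen", list(kind = "scheduled"),
                                      "ra")
  ires <- enterValue(rig$store, defn, rig$ra, ikey, "hb_gdl", 22)
  sig <- function(flags) sort(vapply(flags, function(f)
    paste(f$kind, f$severity, f$variable), character(1)))
  expect_identical(sig(ires$flags), unname(sig(pend)))
})

test_that("exported CRF tables survive an import round trip into a fresh store", {
  fx <- getFixture("mumbai-like")
  defn <- fx$definition
  rig <- rigStore(defn)
  registerDevice(rig$store, "01")
  pids <- vapply(1:4, function(i)
    registerParticipant(rig$store, defn, rig$ra, dobExact(Sys.Date() - 450)),
    character(1))
  importExternalResults(rig$store, defn, rig$ra,
                        makeLabFile(pids, c(9.5, 11, 12.5, 14)), "lab_screen")
  out1 <- exportTables(rig$store, defn, rig$dm, tempfile())

  rig2 <- rigStore(defn, device = "01")
  registerDevice(rig2$store, "01")
  for (i in seq_along(pids)) {
    registerParticipant(rig2$store, defn, rig2$ra, dobExact(Sys.Date() - 450))
  }
  tab <- utils::read.csv(out1[["lab_screen"]], check.names = FALSE)
  importExternalResults(rig2$store, defn, rig2$ra,
                        tab[, c("personal_id", "hb_gdl")], "lab_screen")
  out2 <- exportTables(rig2$store, defn, rig2$dm, tempfile())
  t1 <- utils::read.csv(out1[["lab_screen"]], check.names = FALSE)
  t2 <- utils::read.csv(out2[["lab_screen"]], check.names = FALSE)
  cols <- c("personal_id", "visit_id", "ordinal", "hb_gdl", "status")
  expect_identical(t1[, cols], t2[, cols])
})
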