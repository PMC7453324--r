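test_that("authentication verifies digests, logs failures, honors deactivation", {
  defn <- miniStudy()
  rig <- rigStore(defn)
  ses <- authenticate(rig$store, "ra", "ra-pw")
  expect_identical(ses$role, "research-assistant")

  expect_error(authenticate(rig$store, "ra", "wrong"), class = "edc_auth_error")
  expect_error(authenticate(rig$store, "ghost", "x"), class = "edc_auth_error")
  fails <- Filter(function(r) identical(r$new$outcome, "failed"),
                  auditHistory(rig$store, "auth_log"))
  expect_length(fails, 2)

  deactivateUser(rig$store, rig$dm, "ra")
  expect_error(authenticate(rig$store, "ra", "ra-pw"), class = "edc_auth_error")
  # passwords are never stored in clear
  acct <- rig$store$state$users[["ra"]]
  expect_false(identical(acct$digest, "ra-pw"))
  expect_match(acct$digest, "^[0-9a-f]{64}$")
})

test_that("the permission matrix gates actions by role", {
  defn <- miniStudy()
  rig <- rigStore(defn)
  ra <- rig$ra; dm <- rig$dm
  expect_true(authorize(ra, "enter-data"))
  expect_true(authorize(ra, "create-participant"))
  expect_true(authorize(ra, "sign"))
  expect_false(authorize(ra, "edit-signed"))
  expect_false(authorize(ra, "export"))
  expect_true(authorize(dm, "export"))
  expect_true(authorize(dm, "edit-signed"))
  # a denial through the enforcing path is audit-logged
  expect_error(exportTables(rig$store, defn, ra, tempfile()),
               class = "edc_permission_error")
  denies <- Filter(function(r) identical(r$new$outcome, "denied"),
                   auditHistory(rig$store, "auth_log"))
  expect_identical(denies[[1]]$new$action, "export")
})

test_that("single-writer push replicates the client exactly and is idempotent", {
  defn <- miniStudy()
  server <- createServerStore(defn)
  addUser(server, "dm", "dm-pw", "data-manager")
  client <- createStore(defn, "01")
  syncStores(client, server, "pull")
  ra_ses <- local({
    dm <- authenticate(client, "dm", "dm-pw")
    addUser(client, "ra", "ra-pw", "research-assistant", session = dm)
    authenticate(client, "ra", "ra-pw")
  })
  pid <- registerParticipant(client, defn, ra_ses, dobExact("1990-01-01"))
  instantiateSchedule(client, defn, ra_ses, pid)
  n_local <- client$counter

  rep1 <- syncStores(client, server, "push")
  expect_identical(rep1$pushed, as.integer(n_local))
  expect_identical(stateSnapshot(server), stateSnapshot(client))
  rep2 <- syncStores(client, server, "both")
  expect_identical(rep2$pushed + rep2$pulled, 0L)
})

test_that("devices editing disjoint participants converge with zero conflicts", {
  fx <- getFixture("surveillance-like")
  sim <- simulateSessions(fx, n_participants = 6, n_devices = 3, seed = 21,
                          error_rate = 0)
  snaps <- c(list(stateSnapshot(sim$server)),
             lapply(sim$clients, stateSnapshot))
  for (s in snaps[-1]) expect_identical(s, snaps[[1]])
  expect_length(sim$server$state$conflicts, 0)
  # oracle: the server state equals a from-scratch fold of its merged log
  expect_identical(replayLog(sim$server)$crfs, sim$server$state$crfs)
  expect_identical(replayLog(sim$server)$participants,
                   sim$server$state$participants)
})

conflictRig <- function() {
  defn <- miniStudy(crf_ids = "a")
  server <- createServerStore(defn)
  addUser(server, "dm", "dm-pw", "data-manager")
  dm0 <- authenticate(server, "dm", "dm-pw")
  addUser(server, "ra", "ra-pw", "research-assistant", session = dm0)
  c1 <- createStore(defn, "01"); c2 <- createStore(defn, "02")
  syncStores(c1, server, "pull"); syncStores(c2, server, "pull")
  s1 <- authenticate(c1, "ra", "ra-pw")
  pid <- registerParticipant(c1, defn, s1, dobExact("1990-01-01"))
  instantiateSchedule(c1, defn, s1, pid)
  key <- paste(pid, "v1", "a", 1, sep = "|")
  enterValue(c1, defn, s1, key, "x", 1)
  syncStores(c1, server, "both"); syncStores(c2, server, "both")
  s2 <- authenticate(c2, "ra", "ra-pw")
  list(defn = defn, server = server, c1 = c1, c2 = c2, s1 = s1, s2 = s2,
       pid = pid, key = key)
}

test_that("concurrent edits of one field yield exactly one conflict with full history", {
  r <- conflictRig()
  enterValue(r$c1, r$defn, r$s1, r$key, "x", 5)   # offline edit on device 01
  enterValue(r$c2, r$defn, r$s2, r$key, "x", 9)   # offline edit on device 02
  syncStores(r$c1, r$server, "push")
  syncStores(r$c2, r$server, "push")

  confs <- listConflicts(r$server)
  expect_length(confs, 1)
  cf <- confs[[1]]
  cand_vals <- c(cf$candidates$local$value, cf$candidates$incoming$value)
  expect_setequal(cand_vals, c(5, 9))
  # both offline values are retained in the audit trail
  hist_vals <- unlist(lapply(auditHistory(r$server, "crfs", r$key),
                             function(h) if (identical(h$field, "values.x")) h$new))
  expect_true(all(c(5, 9) %in% hist_vals))
  # provisional winner: higher logical timestamp, deterministic
  expect_identical(r$server$state$crfs[[r$key]]$values$x, cf$provisional)

  # resolution is privilege-gated and audited
  ra_srv <- authenticate(r$server, "ra", "ra-pw")
  expect_error(resolveConflict(r$server, ra_srv, cf$conflict_id, 5),
               class = "edc_permission_error")
  dm_srv <- authenticate(r$server, "dm", "dm-pw")
  resolveConflict(r$server, dm_srv, cf$conflict_id, 5)
  expect_identical(r$server$state$crfs[[r$key]]$values$x, 5)
  expect_true(r$server$state$conflicts[[cf$conflict_id]]$resolved)
})

test_that("the provisional tie-break prefers the lexicographically smaller device", {
  r <- conflictRig()
  # engineer equal logical timestamps by making both edits the same ordinal
  # change on each client
  enterValue(r$c1, r$defn, r$s1, r$key, "x", 5)
  enterValue(r$c2, r$defn, r$s2, r$key, "x", 9)
  ts1 <- r$c1$log[[length(r$c1$log)]]$logical_ts
  ts2 <- r$c2$log[[length(r$c2$log)]]$logical_ts
  syncStores(r$c1, r$server, "push")
  syncStores(r$c2, r$server, "push")
  cf <- listConflicts(r$server)[[1]]
  expected <- if (ts2 > ts1) 9 else if (ts2 < ts1) 5 else {
    if ("02" < "01") 9 else 5
  }
  expect_identical(cf$provisional, expected)
})

test_that("a scoped pull never transfers out-of-scope participant records", {
  fx <- getFixture("surveillance-like")
  defn <- fx$definition
  server <- createServerStore(defn)
  addUser(server, "dm", "dm-pw", "data-manager")
  dm0 <- authenticate(server, "dm", "dm-pw")
  addUser(server, "ra", "ra-pw", "research-assistant", session = dm0)
  c1 <- createStore(defn, "01")
  syncStores(c1, server, "pull")
  s1 <- authenticate(c1, "ra", "ra-pw")
  pidA <- registerParticipant(c1, defn, s1, dobExact("1994-01-01"))
  pidB <- registerParticipant(c1, defn, s1, dobExact("1995-01-01"))
  instantiateSchedule(c1, defn, s1, pidA)
  instantiateSchedule(c1, defn, s1, pidB)
  syncStores(c1, server, "push")

  station <- createStore(defn, "03")
  syncStores(station, server, "pull", scope = list(participants = pidA))
  expect_false(is.null(station$state$participants[[pidA]]))
  expect_null(station$state$participants[[pidB]])
  for (rec in station$log) {
    if (!is.null(rec$meta$participant)) {
      expect_identical(rec$meta$participant, pidA)
    }
  }
})

test_that("purge refuses with unsynced records, then erases data but keeps counters", {
  defn <- miniStudy()
  server <- createServerStore(defn)
  addUser(server, "dm", "dm-pw", "data-manager")
  client <- createStore(defn, "01")
  syncStores(client, server, "pull")
  dm <- authenticate(client, "dm", "dm-pw")
  pid1 <- registerParticipant(client, defn, dm, dobExact("1990-01-01"))
  expect_error(purgeDevice(client, dm, confirm = TRUE),
               class = "edc_state_error")
  expect_match(tryCatch(purgeDevice(client, dm, confirm = TRUE),
                        error = conditionMessage), "[0-9]+ change record")

  syncStores(client, server, "push")
  counter_before <- client$counter
  purgeDevice(client, dm, confirm = TRUE)
  expect_length(client$state$participants, 0)
  expect_length(client$log, 0)
  expect_identical(client$counter, counter_before)

  # post-purge registrations can never recycle ids or change ids: user
  # accounts and device counters survive the purge, so the device keeps
  # working and every new id is fresh
  dm2 <- authenticate(client, "dm", "dm-pw")
  pid2 <- registerParticipant(client, defn, dm2, dobExact("1991-01-01"))
  expect_false(identical(pid1, pid2))
  new_ids <- vapply(client$log, function(r) r$change_id, character(1))
  server_ids <- vapply(server$log, function(r) r$change_id, character(1))
  own_new <- new_ids[startsWith(new_ids, "01#")]
  expect_gt(length(own_new), 0)
  expect_length(intersect(own_new, server_ids), 0)
})

test_that("audit history chains old to new and folds to the current value", {
  defn <- miniStudy(crf_ids = "a")
  rig <- rigStore(defn)
  pid <- registerParticipant(rig$store, defn, rig$ra, dobExact("1990-01-01"))
  instantiateSchedule(rig$store, defn, rig$ra, pid)
  key <- paste(pid, "v1", "a", 1, sep = "|")
  enterValue(rig$store, defn, rig$ra, key, "x", 1)
  enterValue(rig$store, defn, rig$ra, key, "x", 2)
  hist <- Filter(function(h) identical(h$field, "values.x"),
                 auditHistory(rig$store, "crfs", key))
  expect_length(hist, 2)
  expect_null(hist[[1]]$old)
  expect_identical(hist[[2]]$old, hist[[1]]$new)
  expect_identical(hist[[2]]$new, rig$store$state$crfs[[key]]$values$x)
  expect_length(auditHistory(rig$store, "crfs", "no|such|entity|1"), 0)
})

test_that("stores persist to a single file and restore losslessly", {
  defn <- miniStudy()
  rig <- rigStore(defn)
  pid <- registerParticipant(rig$store, defn, rig$ra, dobExact("1990-01-01"))
  path <- tempfile(fileext = ".edc")
  saveStore(rig$store, path)
  st2 <- loadStore(path)
  expect_identical(stateSnapshot(st2), stateSnapshot(rig$store))
  expect_identical(st2$counter, rig$store$counter)
  expect_identical(length(st2$log), length(rig$store$log))
})
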