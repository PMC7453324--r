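test_that("table loading validates sequence monotonicity and color mapping", {
  fx <- getFixture("mbfc-like")
  defn <- fx$definition
  tab <- fx$rand_table
  expect_s3_class(tab, "edc_rand_table")
  expect_setequal(unique(vapply(tab$rows, function(r) r$color_group,
                                character(1))), c("A", "B", "C", "D"))
  expect_setequal(unique(unlist(tab$color_to_arm)), c("food_basket", "control"))

  empty <- loadRandomizationTable(
    data.frame(sequence_no = integer(0), color_group = character(0)), defn)
  expect_identical(empty$n, 0L)

  bad <- data.frame(sequence_no = c(1, 2, 2), color_group = c("A", "B", "C"))
  expect_error(loadRandomizationTable(bad, defn), class = "edc_table_error")
  unk <- data.frame(sequence_no = 1:2, color_group = c("A", "Z"))
  expect_error(loadRandomizationTable(unk, defn), class = "edc_mapping_error")
})

mbfcEnroll <- function(rig, defn, age_months = 12) {
  pid <- registerParticipant(rig$store, defn, rig$ra,
                             dobExact(Sys.Date() - round(age_months * 30.4)))
  instantiateSchedule(rig$store, defn, rig$ra, pid)
  ck <- paste(pid, "screening", "consent_multilevel", 1, sep = "|")
  fillAndComplete(rig$store, defn, rig$ra, ck,
                  list(consent_screening = "1", consent_storage = "1",
                       consent_future_genetic = "1"),
                  sign_as = list(list(username = "ra", password = "ra-pw")))
  sk <- paste(pid, "screening", "screening_mbfc", 1, sep = "|")
  fillAndComplete(rig$store, defn, rig$ra, sk,
                  list(age_months = age_months, hb_gdl = 11),
                  sign_as = list(list(username = "ra", password = "ra-pw")))
  pid
}

test_that("allocation consumes rows in order with exact arm composition and conservation", {
  fx <- getFixture("mbfc-like")
  defn <- fx$definition
  rig <- rigStore(defn)
  registerDevice(rig$store, "01")
  n <- 10L
  pids <- vapply(seq_len(n), function(i) mbfcEnroll(rig, defn), character(1))
  allocs <- lapply(pids, function(pid)
    allocateParticipant(rig$store, defn, fx$rand_table, rig$ra, pid))

  expect_identical(vapply(allocs, function(a) a$sequence_no, integer(1)),
                   1:n)
  # oracle: count the first n table rows by arm and compare exactly
  oracle_arms <- table(vapply(fx$rand_table$rows[1:n], function(r)
    fx$rand_table$color_to_arm[[r$color_group]], character(1)))
  got_arms <- table(vapply(allocs, function(a) a$arm, character(1)))
  expect_identical(as.list(got_arms), as.list(oracle_arms))
  # conservation: allocations + unconsumed rows == table size
  expect_identical(length(rig$store$state$allocations) +
                     (fx$rand_table$n - n), fx$rand_table$n)

  # enrollment ids carry the color letter
  for (i in seq_len(n)) {
    eid <- rig$store$state$participants[[pids[[i]]]]$enrollment_id
    expect_identical(substr(eid, nchar(eid), nchar(eid)),
                     allocs[[i]]$color_group)
    expect_identical(rig$store$state$participants[[pids[[i]]]]$status,
                     "enrolled")
  }
})

test_that("allocation preconditions: eligibility, consent, capacity, no re-allocation", {
  fx <- getFixture("mbfc-like")
  defn <- fx$definition
  rig <- rigStore(defn)
  registerDevice(rig$store, "01")

  raw <- registerParticipant(rig$store, defn, rig$ra,
                             dobExact(Sys.Date() - 360))
  expect_error(allocateParticipant(rig$store, defn, fx$rand_table, rig$ra, raw),
               class = "edc_state_error")

  pid <- mbfcEnroll(rig, defn)
  allocateParticipant(rig$store, defn, fx$rand_table, rig$ra, pid)
  expect_error(allocateParticipant(rig$store, defn, fx$rand_table, rig$ra, pid),
               class = "edc_duplication_error")

  tiny <- loadRandomizationTable(
    data.frame(sequence_no = 1, color_group = "A"), defn)
  pid2 <- mbfcEnroll(rig, defn)
  expect_error(allocateParticipant(rig$store, defn, tiny, rig$ra, pid2),
               class = "edc_capacity_error")
})

test_that("midline designation instantiates serial-sampling CRFs at exactly the designated visit", {
  fx <- getFixture("mbfc-like")
  defn <- fx$definition
  rig <- rigStore(defn)
  registerDevice(rig$store, "01")
  pids <- vapply(1:6, function(i) mbfcEnroll(rig, defn), character(1))
  for (pid in pids) allocateParticipant(rig$store, defn, fx$rand_table, rig$ra, pid)

  fu_visits <- sprintf("fu%d", 1:9)
  for (pid in pids) {
    alloc <- rig$store$state$allocations[[pid]]
    for (vid in fu_visits) {
      insts <- crfInstancesFor(rig$store, pid, vid, "serial_sample_mbfc")
      expect_length(insts, if (identical(vid, alloc$midline_visit)) 1L else 0L)
    }
  }
  # oracle: union of designated visits equals the table's midline column
  oracle <- vapply(fx$rand_table$rows[1:6], function(r) r$midline_visit,
                   character(1))
  got <- vapply(pids, function(pid)
    rig$store$state$allocations[[pid]]$midline_visit, character(1))
  expect_identical(unname(got), oracle)
})

test_that("device blocks keep concurrent offline allocation conflict-free", {
  fx <- getFixture("mumbai-like")
  defn <- fx$definition
  tab <- assignDeviceBlocks(fx$rand_table, c("01", "02"), block_size = 4)
  expect_length(intersect(tab$blocks[["01"]], tab$blocks[["02"]]), 0)
  expect_setequal(c(tab$blocks[["01"]], tab$blocks[["02"]]), seq_len(tab$n))

  sim <- simulateSessions(fx, n_participants = 8, n_devices = 2, seed = 5,
                          error_rate = 0)
  seqs <- vapply(sim$server$state$allocations, function(a) a$sequence_no,
                 integer(1))
  expect_identical(anyDuplicated(seqs), 0L)
  expect_length(listConflicts(sim$server), 0)
})

test_that("the permuted-block generator balances colors within blocks (testing aid)", {
  df <- makePermutedBlockTable(16, c("A", "B"), seed = 7, block_size = 4)
  expect_identical(df$sequence_no, 1:16)
  for (b in seq_len(4)) {
    block <- df$color_group[((b - 1) * 4 + 1):(b * 4)]
    expect_identical(sort(table(block), decreasing = TRUE)[[1]], 2L)
  }
  expect_identical(makePermutedBlockTable(16, c("A", "B"), seed = 7,
                                          block_size = 4),
                   df)  # seeded determinism
})
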