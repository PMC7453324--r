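## Seeded multi-device enumerator session simulator. Generates registrations,
## plausible entries, deliberate soft-range violations and end-of-day syncs;
## fully reproducible from the seed. The value distributions are arbitrary
## documented choices that exercise validation paths — they are synthetic and
## make no claim of realism.

simClock <- function(origin = "2020-01-06 08:00:00") {
  env <- new.env(parent = emptyenv())
  env$t <- as.POSIXct(origin, tz = "UTC")
  function() {
    env$t <- env$t + 37  # fixed stride keeps timestamps strictly increasing
    env$t
  }
}

simDob <- function(defn, clock_today) {
  ## infant fixtures (randomized designs with an age-in-months criterion)
  ## get infant ages; others get adolescent/adult ages mostly inside the
  ## surveillance band
  infant <- any(grepl("age_months", vapply(defn$criteria, function(k) k$expression,
                                           character(1))))
  age_days <- if (infant) {
    round(stats::runif(1, 300, 640))
  } else if (stats::runif(1) < 0.9) {
    round(stats::runif(1, 16, 39) * 365.25)
  } else {
    round(stats::runif(1, 8, 60) * 365.25)
  }
  birth <- clock_today - age_days
  u <- stats::runif(1)
  if (u < 0.6) {
    dobExact(birth)
  } else if (u < 0.85) {
    yr <- as.integer(format(birth, "%Y"))
    if (stats::runif(1) < 0.5) {
      dobPartial(yr)
    } else {
      dobPartial(yr, as.integer(format(birth, "%m")))
    }
  } else {
    dobStated(completedYears(birth, clock_today), clock_today)
  }
}

simValue <- function(vardef, values, clock_today) {
  if (vardef$type %in% c("choice", "multi-choice")) {
    codes <- vapply(vardef$choices, function(ch) ch$code, character(1))
    if (identical(vardef$name, "pregnancies_count")) return(NULL)
    ## bias toward the first code ("No" for yes/no items) so most
    ## participants pass screening and few triggers fire
    if (length(codes) > 1 && stats::runif(1) < 0.8) return(codes[[1]])
    return(sample(codes, 1))
  }
  if (vardef$type %in% c("integer", "decimal")) {
    sr <- vardef$soft_range
    lo <- sr$low %||% 0; hi <- sr$high %||% 10
    v <- stats::runif(1, lo, hi)
    if (vardef$type == "integer") v <- round(v)
    return(v)
  }
  if (vardef$type == "date") return(as.character(clock_today))
  if (vardef$type %in% c("signature-ref", "attachment-ref")) return("ref:sim")
  "simulated entry"
}

simSoftViolation <- function(vardef) {
  sr <- vardef$soft_range; hr <- vardef$hard_range
  if (is.null(sr)) return(NULL)
  hi_hard <- hr$high %||% (sr$high %||% 0) + 100
  v <- ((sr$high %||% 0) + hi_hard) / 2
  if (vardef$type == "integer") v <- floor(v)
  ## must lie strictly inside the hard range but outside the soft range
  if (!is.null(hr$high) && v >= hr$high) v <- hr$high - 1
  v
}

simFillCrf <- function(store, defn, session, key, error_rate, stats_env) {
  inst <- store$state$crfs[[key]]
  crf <- defn$crfs[[inst$crf_id]]
  replicate_base <- list()
  repeat {
    inst <- store$state$crfs[[key]]
    vis <- visibleVariables(defn, inst$crf_id, inst$values)
    todo <- Filter(function(vn) isBlankValue(inst$values[[vn]]), vis)
    if (length(todo) == 0) break
    vn <- todo[[1]]
    vardef <- crf$variables[[vn]]
    ## correlated reproductive-history values keep cross-field rules quiet
    val <- if (identical(vn, "pregnancies_count")) {
      if (identical(inst$values[["ever_pregnant"]], "1")) {
        sample(1:4, 1)
      } else 0
    } else if (grepl("_r[0-9]+$", vn)) {
      stem <- sub("_r[0-9]+$", "", vn)
      base <- replicate_base[[stem]]
      if (is.null(base)) {
        base <- simValue(vardef, inst$values, as.Date(store$clock()))
        replicate_base[[stem]] <- base
        base
      } else {
        ## usually within the variation threshold, occasionally beyond it
        spread <- if (stats::runif(1) < 0.15) 1.2 else 0.2
        base + stats::runif(1, -spread, spread)
      }
    } else {
      simValue(vardef, inst$values, as.Date(store$clock()))
    }
    if (vardef$type %in% c("integer", "decimal") &&
        !is.null(vardef$soft_range) && !grepl("_r[0-9]+$", vn)) {
      stats_env$opportunities <- stats_env$opportunities + 1L
      if (stats::runif(1) < error_rate) {
        bad <- simSoftViolation(vardef)
        res <- enterValue(store, defn, session, key, vn, bad)
        stats_env$injected <- stats_env$injected + 1L
        stats_env$flags_raised <- stats_env$flags_raised +
          length(Filter(function(f) identical(f$kind, "soft-range"), res$flags))
      }
    }
    enterValue(store, defn, session, key, vn, val, acknowledge = TRUE)
  }
}

simSignCrf <- function(store, defn, key, signers) {
  inst <- store$state$crfs[[key]]
  slots <- defn$crfs[[inst$crf_id]]$signature_slots
  for (s in seq_len(slots)) {
    signCrf(store, defn, key, signers[[s]]$username, signers[[s]]$password)
  }
}

#' Simulate seeded multi-device enumerator sessions
#'
#' Drives a complete field workflow against a fixture: user provisioning,
#' per-device registration (households where the study has them), schedule
#' instantiation, gated data entry with deliberate soft-range violations at
#' `error_rate` per ranged numeric entry, flag acknowledgment, completion,
#' signing, allocation (for randomized fixtures, from per-device table
#' blocks) and end-of-day push/pull synchronization of every device. The
#' run is fully reproducible from `seed`; the same seed yields
#' byte-identical server exports.
#'
#' @param fixture a fixture from [buildFixture()] (or a bare definition for
#'   non-randomized studies).
#' @param n_participants number of participants (split round-robin across
#'   devices).
#' @param n_devices number of capture devices.
#' @param seed RNG seed.
#' @param error_rate probability of injecting one implausible
#'   (soft-range-violating, later corrected) value per ranged numeric
#'   entry.
#' @return list with `server`, `clients`, `script` (event data frame) and
#'   `stats` (opportunities, injected errors, flags raised, eligibility and
#'   allocation counts).
#' @export
simulateSessions <- function(fixture, n_participants = 12, n_devices = 2,
                             seed = 1, error_rate = 0) {
  stopifnot(n_participants >= 1, n_devices >= 1,
            error_rate >= 0, error_rate <= 1)
  defn <- if (inherits(fixture, "edc_study_definition")) fixture else fixture$definition
  table <- if (is.list(fixture) && !inherits(fixture, "edc_study_definition")) {
    fixture$rand_table
  } else NULL

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  clock <- simClock()
  server <- createServerStore(defn, clock = clock)
  dm <- addUser(server, "dm1", "dm-pass", "data-manager")
  device_codes <- sprintf("%02d", seq_len(n_devices))
  for (d in device_codes) {
    addUser(server, paste0("ra", d, "a"), "ra-pass", "research-assistant",
            session = authenticate(server, "dm1", "dm-pass"))
    addUser(server, paste0("ra", d, "b"), "ra-pass", "research-assistant",
            session = authenticate(server, "dm1", "dm-pass"))
  }
  clients <- lapply(device_codes, function(d) createStore(defn, d, clock = clock))
  names(clients) <- device_codes
  for (cl in clients) syncStores(cl, server, "pull")

  ## schemes without a device-code component need pre-assigned disjoint
  ## sequential ranges to stay collision-free across offline devices
  has_devcode <- any(vapply(defn$id_scheme$participant,
                            function(cp) cp$component == "device-code",
                            logical(1)))
  if (!has_devcode) {
    for (j in seq_along(device_codes)) {
      registerDevice(clients[[j]], device_codes[[j]],
                     seq_start = (j - 1L) * 1000L + 1L)
    }
  }

  if (!is.null(table)) table <- assignDeviceBlocks(table, device_codes)

  script <- list()
  note <- function(device, action, participant, detail = "") {
    script[[length(script) + 1L]] <<- data.frame(
      step = length(script) + 1L, device = device, action = action,
      participant = participant, detail = detail, stringsAsFactors = FALSE)
  }
  stats_env <- new.env(parent = emptyenv())
  stats_env$opportunities <- 0L
  stats_env$injected <- 0L
  stats_env$flags_raised <- 0L
  n_eligible <- 0L; n_ineligible <- 0L; n_allocated <- 0L
  last_household <- list()

  for (i in seq_len(n_participants)) {
    d <- device_codes[[(i - 1L) %% n_devices + 1L]]
    cl <- clients[[d]]
    signers <- list(
      list(username = paste0("ra", d, "a"), password = "ra-pass"),
      list(username = paste0("ra", d, "b"), password = "ra-pass")
    )
    ses <- authenticate(cl, signers[[1]]$username, signers[[1]]$password)
    hh <- NULL
    if (!is.null(defn$id_scheme$household)) {
      if (is.null(last_household[[d]]) || stats::runif(1) < 0.8) {
        hh <- registerHousehold(cl, defn, ses,
                                attributes = list(village = sample(LETTERS[1:5], 1)))
        last_household[[d]] <- hh
      } else {
        hh <- last_household[[d]]
      }
    }
    dob <- simDob(defn, as.Date(cl$clock()))
    pid <- registerParticipant(cl, defn, ses, dob, household_id = hh,
                               name_fields = list(name_full = sprintf("Participant %03d", i)))
    note(d, "register", pid, dob$kind)
    instantiateSchedule(cl, defn, ses, pid)

    guard <- 0L
    repeat {
      guard <- guard + 1L
      if (guard > 200L) break
      permitted <- gateProgression(cl, defn, pid)
      open <- Filter(function(inst) {
        inst$crf_id %in% permitted && !identical(inst$status, "signed")
      }, crfInstancesFor(cl, pid))
      if (length(open) == 0) break
      inst <- open[[1]]
      key <- inst$instance_key
      ## gating soundness by construction: only permitted CRFs are entered
      simFillCrf(cl, defn, ses, key, error_rate, stats_env)
      done <- tryCatch({ completeCrf(cl, defn, ses, key); TRUE },
                       edc_flag_error = function(e) FALSE)
      if (!done) {
        for (fid in names(pendingFlags(cl, key))) {
          acknowledgeFlag(cl, ses, key, fid)
        }
        completeCrf(cl, defn, ses, key)
      }
      simSignCrf(cl, defn, key, signers)
      note(d, "complete+sign", pid, inst$crf_id)

      elig <- cl$state$eligibility[[pid]]$overall %||% "pending"
      if (identical(elig, "eligible") && !is.null(table) &&
          is.null(cl$state$allocations[[pid]]) &&
          consentSatisfied(cl, defn, pid)) {
        alloc <- tryCatch(
          allocateParticipant(cl, defn, table, ses, pid),
          edc_capacity_error = function(e) NULL)
        if (!is.null(alloc)) {
          n_allocated <- n_allocated + 1L
          note(d, "allocate", pid,
               sprintf("seq %d color %s", alloc$sequence_no, alloc$color_group))
        }
      }
    }
    elig <- cl$state$eligibility[[pid]]$overall %||% "pending"
    if (identical(elig, "eligible")) n_eligible <- n_eligible + 1L
    if (identical(elig, "ineligible")) n_ineligible <- n_ineligible + 1L

    ## end-of-day synchronization after each day's participant
    for (cl2 in clients) syncStores(cl2, server, "both")
  }
  for (cl2 in clients) syncStores(cl2, server, "both")

  list(server = server, clients = clients,
       script = do.call(rbind, script),
       stats = list(opportunities = stats_env$opportunities,
                    injected = stats_env$injected,
                    flags_raised = stats_env$flags_raised,
                    eligible = n_eligible, ineligible = n_ineligible,
                    allocated = n_allocated))
}
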