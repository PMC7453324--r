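#' Create a client or server data store
#'
#' A store is the unit of persistence and synchronization: one per capture
#' device (client) plus one server store per study. It is event-sourced —
#' every mutation is a `ChangeRecord` (who, when, from which device, which
#' field, old value, new value) appended to the change log, and the
#' materialized state is, at all times, the fold of that log. The change log
#' is simultaneously the audit trail and the synchronization payload.
#'
#' Change identifiers are `device_code` plus a device-local monotone
#' counter, so they are globally unique with no coordination. The counter is
#' never reset (not even by [purgeDevice()]), so a reused device can never
#' recycle an identifier.
#'
#' @param defn compiled study definition the store captures data for.
#' @param device_code short unique code for this capture device; use
#'   `"@server"` (the default of [createServerStore()]) for the server.
#' @param clock zero-argument function returning POSIXct; injectable so
#'   simulations are reproducible. Defaults to [Sys.time()].
#' @return an `edc_store` (environment with reference semantics).
#' @export
createStore <- function(defn, device_code, clock = Sys.time) {
  stopifnot(inherits(defn, "edc_study_definition"))
  st <- new.env(parent = emptyenv())
  st$study_code <- defn$study_code
  st$schema_version <- defn$version
  st$device_code <- device_code
  st$clock <- clock
  st$log <- list()
  st$counter <- 0L          # own-record counter == logical timestamp
  st$acked_through <- 0L    # own records acknowledged by a server
  st$seen <- new.env(parent = emptyenv())  # change_id -> TRUE
  st$watermarks <- list()   # origin device -> max seq applied
  st$sessions <- new.env(parent = emptyenv())
  st$state <- new.env(parent = emptyenv())
  for (entity in c("users", "devices", "households", "participants",
                   "visits", "crfs", "eligibility", "allocations",
                   "conflicts", "auth_log")) {
    st$state[[entity]] <- list()
  }
  class(st) <- "edc_store"
  st
}

#' @rdname createStore
#' @export
createServerStore <- function(defn, clock = Sys.time) {
  createStore(defn, "@server", clock = clock)
}

#' @export
print.edc_store <- function(x, ...) {
  cat(sprintf("<edc_store> %s @ %s | %d change record(s), %d participant(s)\n",
              x$study_code, x$device_code, length(x$log),
              length(x$state$participants)))
  invisible(x)
}

## ---- field paths -------------------------------------------------------

getFieldPath <- function(store, entity, key, field) {
  obj <- store$state[[entity]][[key]]
  if (is.null(obj)) return(NULL)
  parts <- strsplit(field, ".", fixed = TRUE)[[1]]
  if (length(parts) == 1) obj[[field]] else obj[[parts[[1]]]][[parts[[2]]]]
}

setFieldPath <- function(store, entity, key, field, value) {
  ents <- store$state[[entity]]
  obj <- ents[[key]] %||% list()
  if (identical(field, "__init__")) {
    obj <- value
  } else {
    parts <- strsplit(field, ".", fixed = TRUE)[[1]]
    if (length(parts) == 1) {
      obj[[field]] <- value
    } else {
      sub <- obj[[parts[[1]]]] %||% list()
      sub[[parts[[2]]]] <- value
      obj[[parts[[1]]]] <- sub
    }
  }
  ents[[key]] <- obj
  store$state[[entity]] <- ents
  invisible(NULL)
}

## ---- change records ----------------------------------------------------

#' Record a local change (the only mutation path)
#' @noRd
recordChange <- function(store, entity, key, field, new, username,
                         meta = NULL) {
  old <- if (identical(field, "__init__")) NULL else getFieldPath(store, entity, key, field)
  seq <- store$counter + 1L
  rec <- list(
    change_id = sprintf("%s#%06d", store$device_code, seq),
    device = store$device_code,
    seq = seq,
    entity = entity, key = key, field = field,
    old = old, new = new,
    username = username,
    logical_ts = seq,
    wall_ts = formatTs(store$clock()),
    schema_version = store$schema_version,
    meta = meta
  )
  store$log[[length(store$log) + 1L]] <- rec
  store$seen[[rec$change_id]] <- TRUE
  store$counter <- seq
  store$watermarks[[store$device_code]] <- seq
  setFieldPath(store, entity, key, field, new)
  invisible(rec)
}

#' Rebuild materialized state by folding the change log
#'
#' The store invariant is that materialized state always equals this fold;
#' [replayLog()] performs it from scratch (used by integrity checks and by
#' tests as the independent oracle for state).
#'
#' @param store an `edc_store`.
#' @return a fresh state environment (not installed into the store).
#' @export
replayLog <- function(store) {
  shadow <- new.env(parent = emptyenv())
  shadow$state <- new.env(parent = emptyenv())
  for (entity in names(as.list(store$state))) shadow$state[[entity]] <- list()
  for (rec in store$log) {
    setFieldPath(shadow, rec$entity, rec$key, rec$field, rec$new)
  }
  shadow$state
}

#' Ordered change history for one entity
#'
#' The complete audit trail for an entity: every field change in application
#' order, including edits to signed CRFs, flag acknowledgments and conflict
#' resolutions, each with username, device, timestamps and old/new values.
#'
#' @param store an `edc_store`.
#' @param entity entity kind (`"crfs"`, `"participants"`, ...).
#' @param key entity key; `NULL` for all of the kind.
#' @return list of change records in application order.
#' @export
auditHistory <- function(store, entity, key = NULL) {
  Filter(function(r) {
    r$entity == entity && (is.null(key) || identical(r$key, key))
  }, store$log)
}

## ---- accounts, authentication, authorization ---------------------------

.edcRoles <- c("research-assistant", "research-coordinator",
               "principal-investigator", "data-manager", "systems-integrator")

.edcPermissionMatrix <- list(
  "research-assistant"     = c("create-participant", "enter-data", "sign"),
  "research-coordinator"   = c("create-participant", "enter-data", "sign",
                               "edit-signed", "resolve-query"),
  "principal-investigator" = c("create-participant", "enter-data", "sign",
                               "edit-signed", "resolve-query", "export"),
  "data-manager"           = c("create-participant", "enter-data", "sign",
                               "edit-signed", "resolve-query", "export",
                               "manage-schema", "manage-users", "purge"),
  "systems-integrator"     = c("manage-schema", "manage-users", "purge")
)

passwordDigest <- function(password, salt) {
  digest::digest(paste0(salt, "\r", password), algo = "sha256", serialize = FALSE)
}

#' Manage user accounts
#'
#' Accounts carry a role from the study-team model (research assistant,
#' research coordinator, principal investigator, data manager, systems
#' integrator). Passwords are stored only as salted SHA-256 digests.
#' Deactivated accounts can no longer authenticate, but their historical
#' signatures remain valid.
#'
#' @param store an `edc_store`.
#' @param session a session with `manage-users` privilege; `NULL` is
#'   permitted only while the store has no users (bootstrap).
#' @param username,password,role account fields.
#' @export
addUser <- function(store, username, password, role, session = NULL) {
  if (!role %in% .edcRoles) {
    edcStop("edc_definition_error", "unknown role '%s'", role)
  }
  if (length(store$state$users) > 0) {
    requirePrivilege(store, session, "manage-users")
  }
  if (!is.null(store$state$users[[username]])) {
    edcStop("edc_uniqueness_error", "username '%s' already exists", username)
  }
  salt <- paste(sprintf("%02x", sample.int(256L, 16L, replace = TRUE) - 1L),
                collapse = "")
  actor <- if (is.null(session)) "@bootstrap" else session$username
  recordChange(store, "users", username, "__init__",
               list(username = username, salt = salt,
                    digest = passwordDigest(password, salt),
                    role = role, active = TRUE),
               username = actor)
  invisible(username)
}

#' @rdname addUser
#' @export
deactivateUser <- function(store, session, username) {
  requirePrivilege(store, session, "manage-users")
  if (is.null(store$state$users[[username]])) {
    edcStop("edc_reference_error", "no such user '%s'", username)
  }
  recordChange(store, "users", username, "active", FALSE, session$username)
  invisible(username)
}

#' Authenticate a user and open a session
#'
#' Failure is indistinguishable between an unknown username, a wrong
#' password and a deactivated account; every failed attempt is written to
#' the audit trail.
#'
#' @param store an `edc_store`.
#' @param username,password credentials.
#' @return a session (list with `token`, `username`, `role`).
#' @export
authenticate <- function(store, username, password) {
  acct <- store$state$users[[username]]
  ok <- !is.null(acct) && isTRUE(acct$active) &&
    identical(passwordDigest(password, acct$salt), acct$digest)
  if (!ok) {
    recordChange(store, "auth_log",
                 sprintf("fail-%06d", store$counter + 1L), "__init__",
                 list(username = username, outcome = "failed"),
                 username = username)
    edcStop("edc_auth_error", "authentication failed")
  }
  token <- digest::digest(list(username, store$counter, formatTs(store$clock())),
                          algo = "sha256")
  session <- list(token = token, username = username, role = acct$role)
  store$sessions[[token]] <- session
  session
}

#' Check a session's privilege for an action
#'
#' Pure lookup in the role-permission matrix; a denial is a value, not an
#' error. Denials checked through the enforcing path are audit-logged.
#'
#' @param session a session from [authenticate()].
#' @param action one of `create-participant`, `enter-data`, `sign`,
#'   `edit-signed`, `resolve-query`, `export`, `manage-schema`,
#'   `manage-users`, `purge`.
#' @return `TRUE` (allow) or `FALSE` (deny).
#' @export
authorize <- function(session, action) {
  if (is.null(session$role)) return(FALSE)
  action %in% (.edcPermissionMatrix[[session$role]] %||% character(0))
}

requirePrivilege <- function(store, session, action) {
  if (is.null(session)) {
    edcStop("edc_permission_error", "no session; action '%s' denied", action)
  }
  if (!authorize(session, action)) {
    recordChange(store, "auth_log",
                 sprintf("deny-%06d", store$counter + 1L), "__init__",
                 list(username = session$username, action = action,
                      outcome = "denied"),
                 username = session$username)
    edcStop("edc_permission_error",
            "role '%s' is not permitted to %s", session$role, action)
  }
  invisible(TRUE)
}

## ---- device + registry operations on a store ---------------------------

#' Register a capture device (initializes its sequential id counter)
#'
#' When the identifier scheme embeds a device-code component, counters can
#' start at 1 on every device and identifiers still cannot collide. For
#' schemes without one (e.g. a bare 4-digit + group-letter design), give
#' each device a disjoint `seq_start` range up front — the same
#' pre-partitioning idea used for randomization rows.
#'
#' @param store an `edc_store`.
#' @param device_code the device's code.
#' @param seq_start first sequential number this device may issue.
#' @export
registerDevice <- function(store, device_code, seq_start = 1L) {
  if (is.null(store$state$devices[[device_code]])) {
    recordChange(store, "devices", device_code, "__init__",
                 list(device_code = device_code,
                      next_sequential = as.integer(seq_start)),
                 username = "@system")
  }
  invisible(device_code)
}

nextSequential <- function(store, device_code) {
  dev <- store$state$devices[[device_code]]
  if (is.null(dev)) edcStop("edc_reference_error",
                            "device '%s' is not registered", device_code)
  n <- dev$next_sequential
  recordChange(store, "devices", device_code, "next_sequential", n + 1L,
               username = "@system")
  n
}

#' Register a household
#'
#' @param store an `edc_store`.
#' @param defn compiled study definition.
#' @param session session with `create-participant` privilege.
#' @param attributes named list of household-level values shared by members.
#' @param device_code capturing device (defaults to the store's).
#' @return the generated household id.
#' @export
registerHousehold <- function(store, defn, session, attributes = list(),
                              device_code = store$device_code) {
  requirePrivilege(store, session, "create-participant")
  scheme <- defn$id_scheme$household
  if (is.null(scheme)) {
    edcStop("edc_definition_error", "study has no household id scheme")
  }
  registerDevice(store, device_code)
  seq_no <- nextSequential(store, device_code)
  hid <- generateParticipantId(defn, device_code, seq_no, scope = "household")
  recordChange(store, "households", hid, "__init__",
               list(household_id = hid, attributes = attributes,
                    device_code = device_code),
               username = session$username)
  hid
}

#' Register a participant and generate their identifier offline
#'
#' The identifier is generated from the study's scheme using the device's
#' own counter — no server round-trip — and therefore cannot collide with
#' identifiers generated on other devices. For randomized designs whose
#' scheme includes a group-letter component, the registration identifier is
#' provisional (letterless); the final enrollment identifier is set at
#' allocation.
#'
#' @param store an `edc_store`.
#' @param defn compiled study definition.
#' @param session session with `create-participant` privilege.
#' @param dob an `edc_dob` (see [dobExact()]).
#' @param name_fields named list of identifying name fields (stripped on
#'   deidentified export).
#' @param household_id optional household reference.
#' @param device_code capturing device (defaults to the store's).
#' @return the participant's personal id.
#' @export
registerParticipant <- function(store, defn, session, dob,
                                name_fields = list(), household_id = NULL,
                                device_code = store$device_code) {
  requirePrivilege(store, session, "create-participant")
  stopifnot(inherits(dob, "edc_dob"))
  if (!is.null(household_id) && is.null(store$state$households[[household_id]])) {
    edcStop("edc_reference_error", "unknown household '%s'", household_id)
  }
  registerDevice(store, device_code)
  seq_no <- nextSequential(store, device_code)
  pid <- generateParticipantId(defn, device_code, seq_no, partial = TRUE)
  if (!is.null(store$state$participants[[pid]])) {
    edcStop("edc_uniqueness_error", "participant id '%s' already exists", pid)
  }
  recordChange(store, "participants", pid, "__init__",
               list(personal_id = pid,
                    household_id = household_id,
                    name_fields = name_fields,
                    dob = unclass(dob),
                    status = "registered",
                    enrollment_id = NULL,
                    device_code = device_code,
                    id_seq = seq_no,
                    registered_at = formatTs(store$clock())),
               username = session$username, meta = list(participant = pid))
  ## age-only criteria (via the participant pseudo-CRF) can exclude at
  ## registration, before any CRF exists
  if (length(defn$criteria) > 0) evaluateEligibility(store, defn, pid)
  pid
}

setParticipantStatus <- function(store, pid, new_status, username,
                                 force = FALSE) {
  p <- store$state$participants[[pid]]
  if (is.null(p)) edcStop("edc_reference_error", "unknown participant '%s'", pid)
  if (identical(p$status, new_status)) return(invisible(NULL))
  if (!force && !statusTransitionAllowed(p$status, new_status)) {
    edcStop("edc_state_error", "participant '%s': cannot move from %s to %s",
            pid, p$status, new_status)
  }
  recordChange(store, "participants", pid, "status", new_status, username,
               meta = list(participant = pid))
  invisible(NULL)
}

#' Participant age helper used by eligibility and consent routing
#' @noRd
participantAge <- function(store, pid, as_of = as.Date(store$clock())) {
  p <- store$state$participants[[pid]]
  dob <- structure(p$dob, class = "edc_dob")
  computeAge(dob, as_of)
}

## ---- persistence (runtime artifact) ------------------------------------

#' Persist / restore a store to a single file
#'
#' The single-file embedded format used by clients and the server alike.
#' Clock functions are not serialized; the restored store ticks with
#' [Sys.time()] unless a clock is supplied.
#'
#' @param store an `edc_store`.
#' @param path file path.
#' @param clock clock function for the restored store.
#' @export
saveStore <- function(store, path) {
  snap <- list(
    study_code = store$study_code, schema_version = store$schema_version,
    device_code = store$device_code, log = store$log,
    counter = store$counter, acked_through = store$acked_through,
    watermarks = store$watermarks,
    seen = ls(store$seen),
    state = lapply(as.list(store$state), identity)
  )
  saveRDS(snap, path)
  invisible(path)
}

#' @rdname saveStore
#' @export
loadStore <- function(path, clock = Sys.time) {
  snap <- readRDS(path)
  st <- new.env(parent = emptyenv())
  st$study_code <- snap$study_code
  st$schema_version <- snap$schema_version
  st$device_code <- snap$device_code
  st$clock <- clock
  st$log <- snap$log
  st$counter <- snap$counter
  st$acked_through <- snap$acked_through
  st$watermarks <- snap$watermarks
  st$seen <- new.env(parent = emptyenv())
  for (id in snap$seen) st$seen[[id]] <- TRUE
  st$sessions <- new.env(parent = emptyenv())
  st$state <- new.env(parent = emptyenv())
  for (entity in names(snap$state)) st$state[[entity]] <- snap$state[[entity]]
  class(st) <- "edc_store"
  st
}
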