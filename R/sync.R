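## Asynchronous client/server synchronization by change-log shipping.

scopeMatches <- function(rec, scope) {
  if (is.null(scope)) return(TRUE)
  if (!is.null(scope$participants) && !is.null(rec$meta$participant)) {
    return(rec$meta$participant %in% scope$participants)
  }
  if (!is.null(scope$entities)) {
    return(rec$entity %in% scope$entities)
  }
  FALSE
}

lastWriterTs <- function(store, entity, key, field) {
  for (i in rev(seq_along(store$log))) {
    r <- store$log[[i]]
    if (identical(r$entity, entity) && identical(r$key, key) &&
        identical(r$field, field)) {
      return(list(logical_ts = r$logical_ts, device = r$device))
    }
  }
  NULL
}

#' Apply a change record that originated on another store
#'
#' Order-preserving per origin device, idempotent by change id. A record
#' whose expected old value matches neither the current value nor its own
#' new value signals concurrent edits of the same field: the incoming
#' value is still appended to the log (history is never dropped), a
#' conflict record capturing both candidates is created, and the field is
#' set to the deterministic provisional winner (higher logical timestamp;
#' tie broken toward the lexicographically smaller device code) pending
#' human resolution.
#' @noRd
applyForeignRecord <- function(store, rec) {
  if (isTRUE(store$seen[[rec$change_id]])) return("skipped")
  conflict <- FALSE
  if (!identical(rec$field, "__init__")) {
    cur <- getFieldPath(store, rec$entity, rec$key, rec$field)
    if (!is.null(store$state[[rec$entity]][[rec$key]]) &&
        !identical(cur, rec$old) && !identical(cur, rec$new)) {
      conflict <- TRUE
      local_writer <- lastWriterTs(store, rec$entity, rec$key, rec$field)
    }
  }
  store$log[[length(store$log) + 1L]] <- rec
  store$seen[[rec$change_id]] <- TRUE
  prev <- store$watermarks[[rec$device]] %||% 0L
  store$watermarks[[rec$device]] <- max(prev, rec$seq)
  if (!conflict) {
    setFieldPath(store, rec$entity, rec$key, rec$field, rec$new)
    return("applied")
  }
  ## record both candidates, then materialize the provisional winner
  setFieldPath(store, rec$entity, rec$key, rec$field, rec$new)
  cand_local <- list(value = cur,
                     device = local_writer$device %||% store$device_code,
                     logical_ts = local_writer$logical_ts %||% 0L)
  cand_in <- list(value = rec$new, device = rec$device,
                  logical_ts = rec$logical_ts)
  win <- if (cand_in$logical_ts > cand_local$logical_ts) {
    cand_in
  } else if (cand_in$logical_ts < cand_local$logical_ts) {
    cand_local
  } else if (cand_in$device < cand_local$device) {
    cand_in
  } else {
    cand_local
  }
  cid <- sprintf("c%06d", length(store$state$conflicts) + 1L)
  recordChange(store, "conflicts", cid, "__init__",
               list(conflict_id = cid, entity = rec$entity, key = rec$key,
                    field = rec$field,
                    candidates = list(local = cand_local, incoming = cand_in),
                    provisional = win$value, resolved = FALSE,
                    chosen = NULL, resolved_by = NULL),
               username = "@sync", meta = rec$meta)
  recordChange(store, rec$entity, rec$key, rec$field, win$value,
               username = "@sync",
               meta = c(rec$meta, list(provisional = TRUE, conflict = cid)))
  "conflict"
}

transferRecords <- function(src, dst, scope) {
  applied <- 0L; conflicts <- 0L
  for (rec in src$log) {
    if (isTRUE(dst$seen[[rec$change_id]])) next
    if (!scopeMatches(rec, scope)) next
    out <- applyForeignRecord(dst, rec)
    if (out == "applied") applied <- applied + 1L
    if (out == "conflict") { applied <- applied + 1L; conflicts <- conflicts + 1L }
  }
  list(applied = applied, conflicts = conflicts)
}

#' Synchronize a client store with a server store
#'
#' Change-log shipping with per-device watermarks: `push` transfers client
#' records the server has not seen, `pull` the reverse (optionally limited
#' to a scope, so a station pulls only its own participants' data — one
#' direction and a narrow scope minimize traffic and preserve privacy).
#' Replay is order-preserving per origin device; the operation is
#' idempotent (a second run transfers nothing) and resumable (every
#' applied record is durable immediately). After both-direction
#' synchronization of all devices against one server, all stores
#' materialize identical state for the shared scope. Concurrent edits of
#' the same field surface as conflict records, never silent overwrites.
#'
#' @param client,server `edc_store`s sharing a study code.
#' @param direction `"push"`, `"pull"` or `"both"`.
#' @param scope optional list with `participants` (ids) or `entities`
#'   (entity kinds) limiting what a *pull* transfers; pushes are never
#'   scoped (a capture device holds primary data the server must get).
#' @return sync report: counts pushed/pulled and conflicts detected.
#' @export
syncStores <- function(client, server, direction = c("both", "push", "pull"),
                       scope = NULL) {
  direction <- match.arg(direction)
  if (!identical(client$study_code, server$study_code)) {
    edcStop("edc_version_error", "stores belong to different studies")
  }
  if (client$schema_version < server$schema_version && direction == "push") {
    edcStop("edc_version_error",
            "client schema v%d is behind server v%d; pull the schema first",
            client$schema_version, server$schema_version)
  }
  pushed <- list(applied = 0L, conflicts = 0L)
  pulled <- list(applied = 0L, conflicts = 0L)
  if (direction %in% c("push", "both")) {
    pushed <- transferRecords(client, server, scope = NULL)
    client$acked_through <- client$counter
  }
  if (direction %in% c("pull", "both")) {
    pulled <- transferRecords(server, client, scope = scope)
  }
  list(pushed = pushed$applied, pulled = pulled$applied,
       conflicts = pushed$conflicts + pulled$conflicts)
}

#' Conflicts awaiting resolution
#'
#' @param store an `edc_store`.
#' @return named list of unresolved conflict records.
#' @export
listConflicts <- function(store) {
  Filter(function(c) !isTRUE(c$resolved), store$state$conflicts)
}

#' Resolve a synchronization conflict
#'
#' Requires the `resolve-query` privilege. The chosen value is
#' materialized; both candidates and the resolution decision remain in the
#' audit trail.
#'
#' @param store an `edc_store`.
#' @param session resolving session.
#' @param conflict_id conflict identifier.
#' @param chosen the value to keep.
#' @export
resolveConflict <- function(store, session, conflict_id, chosen) {
  requirePrivilege(store, session, "resolve-query")
  cf <- store$state$conflicts[[conflict_id]]
  if (is.null(cf)) edcStop("edc_reference_error", "no conflict '%s'", conflict_id)
  recordChange(store, "conflicts", conflict_id, "resolved", TRUE, session$username)
  recordChange(store, "conflicts", conflict_id, "chosen", chosen, session$username)
  recordChange(store, "conflicts", conflict_id, "resolved_by", session$username,
               session$username)
  recordChange(store, cf$entity, cf$key, cf$field, chosen, session$username,
               meta = list(resolution = conflict_id))
  invisible(conflict_id)
}

#' Purge study data from a device after study completion
#'
#' Refuses while the device holds records the server has not acknowledged.
#' Participant data and the change log are erased; the device identity and
#' its counters survive, so identifiers and change ids generated after a
#' purge can never collide with pre-purge ones.
#'
#' @param client a client `edc_store`.
#' @param session session with `purge` privilege.
#' @param confirm must be `TRUE`.
#' @export
purgeDevice <- function(client, session, confirm = FALSE) {
  requirePrivilege(client, session, "purge")
  if (!isTRUE(confirm)) {
    edcStop("edc_state_error", "purge requires explicit confirmation")
  }
  pending <- client$counter - client$acked_through
  if (pending > 0) {
    edcStop("edc_state_error",
            "%d change record(s) not yet acknowledged by the server; sync before purging",
            pending)
  }
  for (entity in c("households", "participants", "visits", "crfs",
                   "eligibility", "allocations", "conflicts")) {
    client$state[[entity]] <- list()
  }
  client$log <- list()
  client$seen <- new.env(parent = emptyenv())
  invisible(client)
}
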