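## Longitudinal protocol enforcement: visit/CRF lifecycle, conditional CRFs,
## consent routing and progression gating, completion and signing.

visitKey <- function(pid, visit_id) paste(pid, visit_id, sep = "|")
crfKey <- function(pid, visit_id, crf_id, ordinal) {
  paste(pid, visit_id, crf_id, ordinal, sep = "|")
}

#' CRF instances of one participant
#'
#' @param store an `edc_store`.
#' @param pid participant id.
#' @param visit_id,crf_id optional filters.
#' @param include_surplus include instances retired by trigger
#'   reconciliation.
#' @return named list of instances keyed by instance key.
#' @export
crfInstancesFor <- function(store, pid, visit_id = NULL, crf_id = NULL,
                            include_surplus = FALSE) {
  out <- list()
  for (key in names(store$state$crfs)) {
    inst <- store$state$crfs[[key]]
    if (!identical(inst$participant, pid)) next
    if (!is.null(visit_id) && !identical(inst$visit_id, visit_id)) next
    if (!is.null(crf_id) && !identical(inst$crf_id, crf_id)) next
    if (!include_surplus && isTRUE(inst$surplus)) next
    out[[key]] <- inst
  }
  out
}

createCrfInstance <- function(store, defn, pid, visit_id, crf_id, origin,
                              username) {
  existing <- crfInstancesFor(store, pid, visit_id, crf_id,
                              include_surplus = TRUE)
  ordinal <- if (length(existing) == 0) 1L else {
    max(vapply(existing, function(i) i$ordinal, integer(1))) + 1L
  }
  key <- crfKey(pid, visit_id, crf_id, ordinal)
  recordChange(store, "crfs", key, "__init__",
               list(instance_key = key, participant = pid,
                    visit_id = visit_id, crf_id = crf_id, ordinal = ordinal,
                    origin = origin, values = list(), flags = list(),
                    status = "empty", signatures = list(),
                    created_at = formatTs(store$clock()),
                    completed_at = NULL, surplus = FALSE,
                    schema_version = defn$version),
               username = username, meta = list(participant = pid))
  updateVisitStatus(store, defn, pid, visit_id)
  key
}

#' Instantiate the scheduled protocol for a participant
#'
#' Creates one visit instance per scheduled visit, in schedule order, each
#' populated with CRF instances for its always-mode schedule cells.
#' Midline-designated cells wait for the randomization table (see
#' [designateMidlineCrfs()]); trigger-only cells wait for their rule to
#' fire.
#'
#' @param store an `edc_store`.
#' @param defn compiled study definition.
#' @param session session of the acting user.
#' @param pid participant id.
#' @return character vector of visit instance keys, in visit order.
#' @export
instantiateSchedule <- function(store, defn, session, pid) {
  requirePrivilege(store, session, "enter-data")
  if (is.null(store$state$participants[[pid]])) {
    edcStop("edc_reference_error", "unknown participant '%s'", pid)
  }
  keys <- character(0)
  for (vid in unlist(defn$visit_order)) {
    vk <- visitKey(pid, vid)
    if (!is.null(store$state$visits[[vk]])) {
      edcStop("edc_state_error", "schedule already instantiated for '%s'", pid)
    }
    recordChange(store, "visits", vk, "__init__",
                 list(visit_key = vk, participant = pid, visit_id = vid,
                      status = "pending"),
                 username = session$username, meta = list(participant = pid))
    keys <- c(keys, vk)
    ## consent-form cells are instantiated only for the participant's routed
    ## age band, so the wrong consent set never appears on the device
    routed <- tryCatch(requiredConsentForms(store, defn, pid),
                       error = function(e) character(0))
    for (cell in defn$schedule) {
      if (identical(cell$visit_id, vid) && identical(cell$mode, "always")) {
        cf <- defn$crfs[[cell$crf_id]]
        if (isTRUE(cf$is_consent_form) && length(defn$consent_routing) > 0 &&
            !cell$crf_id %in% routed) {
          next
        }
        createCrfInstance(store, defn, pid, vid, cell$crf_id,
                          list(kind = "scheduled"), session$username)
      }
    }
  }
  keys
}

#' Create an on-demand unscheduled visit for a participant
#'
#' @inheritParams instantiateSchedule
#' @param visit_id an unscheduled visit id from the definition, or the
#'   reserved id `"unscheduled"`.
#' @return the visit instance key.
#' @export
createUnscheduledVisit <- function(store, defn, session, pid,
                                   visit_id = "unscheduled") {
  requirePrivilege(store, session, "enter-data")
  vd <- defn$visits[[visit_id]]
  if (!is.null(vd) && isTRUE(vd$scheduled)) {
    edcStop("edc_state_error", "visit '%s' is scheduled, not on-demand", visit_id)
  }
  vk <- visitKey(pid, visit_id)
  if (is.null(store$state$visits[[vk]])) {
    recordChange(store, "visits", vk, "__init__",
                 list(visit_key = vk, participant = pid, visit_id = visit_id,
                      status = "pending"),
                 username = session$username, meta = list(participant = pid))
  }
  vk
}

#' Derived visit status
#'
#' A visit is complete when every contained (non-surplus) CRF instance has
#' been completed and signed; it is pending while no instance has been
#' touched.
#'
#' @param store an `edc_store`.
#' @param defn compiled study definition.
#' @param pid participant id.
#' @param visit_id visit id.
#' @return `"pending"`, `"in-progress"` or `"complete"`.
#' @export
visitStatus <- function(store, defn, pid, visit_id) {
  insts <- crfInstancesFor(store, pid, visit_id)
  if (length(insts) == 0) return("pending")
  statuses <- vapply(insts, function(i) i$status, character(1))
  if (all(statuses == "signed")) return("complete")
  if (all(statuses == "empty")) return("pending")
  "in-progress"
}

updateVisitStatus <- function(store, defn, pid, visit_id) {
  vk <- visitKey(pid, visit_id)
  v <- store$state$visits[[vk]]
  if (is.null(v)) return(invisible(NULL))
  newst <- visitStatus(store, defn, pid, visit_id)
  if (!identical(v$status, newst)) {
    recordChange(store, "visits", vk, "status", newst, "@system",
                 meta = list(participant = pid))
  }
  invisible(NULL)
}

coerceValue <- function(vardef, value) {
  if (isBlankValue(value)) return(NA)
  if (vardef$type %in% c("integer", "decimal")) {
    v <- suppressWarnings(as.numeric(value))
    if (is.na(v)) {
      edcStop("edc_type_error", "'%s' expects a number, got '%s'",
              vardef$name, as.character(value))
    }
    if (vardef$type == "integer" && v != floor(v)) {
      edcStop("edc_type_error", "'%s' expects an integer, got %s",
              vardef$name, format(v))
    }
    return(v)
  }
  if (vardef$type == "date") {
    d <- tryCatch(as.Date(as.character(value)), error = function(e) NA)
    if (is.na(d)) edcStop("edc_type_error", "'%s' expects a date (YYYY-MM-DD)",
                          vardef$name)
    return(as.character(d))
  }
  if (vardef$type %in% c("choice", "multi-choice")) {
    codes <- vapply(vardef$choices, function(ch) ch$code, character(1))
    vals <- if (vardef$type == "multi-choice") splitList(value) else as.character(value)
    bad <- setdiff(vals, codes)
    if (length(bad) > 0) {
      edcStop("edc_type_error", "'%s': invalid choice code(s) %s",
              vardef$name, paste(bad, collapse = ", "))
    }
    return(paste(vals, collapse = ";"))
  }
  as.character(value)
}

activeFlags <- function(inst) {
  Filter(function(f) !isTRUE(f$voided), inst$flags)
}

#' Warn/block flags currently outstanding on a CRF instance
#'
#' @param store an `edc_store`.
#' @param key CRF instance key.
#' @return list of unacknowledged, non-voided flags.
#' @export
pendingFlags <- function(store, key) {
  inst <- store$state$crfs[[key]]
  if (is.null(inst)) edcStop("edc_reference_error", "unknown instance '%s'", key)
  Filter(function(f) is.null(f$acknowledged_by), activeFlags(inst))
}

addFlag <- function(store, key, flag, username, pid) {
  inst <- store$state$crfs[[key]]
  fid <- sprintf("f%04d", length(inst$flags) + 1L)
  flag$flag_id <- fid
  flag$raised_at <- formatTs(store$clock())
  flag$voided <- FALSE
  recordChange(store, "crfs", key, paste0("flags.", fid), flag, username,
               meta = list(participant = pid))
  fid
}

voidFlagsForVariable <- function(store, key, variable, username, pid) {
  inst <- store$state$crfs[[key]]
  for (fid in names(inst$flags)) {
    f <- inst$flags[[fid]]
    if (identical(f$variable, variable) && !isTRUE(f$voided)) {
      f$voided <- TRUE
      recordChange(store, "crfs", key, paste0("flags.", fid), f, username,
                   meta = list(participant = pid))
    }
  }
}

#' Enter a value into a CRF instance
#'
#' The single synchronous data-entry path. The variable must be visible
#' under the current skip-rule, replicate and adaptive evaluation; the
#' value is type-checked against the dictionary and range-checked
#' ([checkValue()]). A hard-range violation blocks storage outright; a
#' soft-range violation stores the value only when entered with
#' `acknowledge = TRUE` (the enumerator has verified it). Every kept value
#' and every flag is written to the audit trail; re-editing a variable
#' voids its earlier flags and acknowledgments.
#'
#' @param store an `edc_store`.
#' @param defn compiled study definition.
#' @param session session with `enter-data` privilege.
#' @param key CRF instance key.
#' @param variable variable name.
#' @param value the value.
#' @param acknowledge set `TRUE` to store despite (and acknowledge) a
#'   soft-range warning.
#' @return invisibly, `list(stored = logical, flags = list)`.
#' @export
enterValue <- function(store, defn, session, key, variable, value,
                       acknowledge = FALSE) {
  requirePrivilege(store, session, "enter-data")
  inst <- store$state$crfs[[key]]
  if (is.null(inst)) edcStop("edc_reference_error", "unknown instance '%s'", key)
  if (identical(inst$status, "signed")) {
    edcStop("edc_permission_error",
            "instance '%s' is signed; use the audited edit path", key)
  }
  crf <- defn$crfs[[inst$crf_id]]
  vardef <- crf$variables[[variable]]
  if (is.null(vardef)) {
    edcStop("edc_reference_error", "no variable '%s' in crf '%s'",
            variable, inst$crf_id)
  }
  if (!variable %in% visibleVariables(defn, inst$crf_id, inst$values)) {
    edcStop("edc_visibility_error",
            "variable '%s' is currently hidden by skip/replicate/adaptive rules",
            variable)
  }
  coerced <- coerceValue(vardef, value)
  flags <- checkValue(vardef, coerced)
  pid <- inst$participant
  voidFlagsForVariable(store, key, variable, session$username, pid)
  severities <- vapply(flags, function(f) f$severity, character(1))
  if (any(severities == "block")) {
    for (f in flags) {
      f$value <- coerced
      addFlag(store, key, f, session$username, pid)
    }
    return(invisible(list(stored = FALSE, flags = flags)))
  }
  if (any(severities == "warn") && !acknowledge) {
    for (f in flags) {
      f$value <- coerced
      addFlag(store, key, f, session$username, pid)
    }
    return(invisible(list(stored = FALSE, flags = flags)))
  }
  for (f in flags) {
    f$value <- coerced
    f$acknowledged_by <- session$username
    f$acknowledged_at <- formatTs(store$clock())
    addFlag(store, key, f, session$username, pid)
  }
  recordChange(store, "crfs", key, paste0("values.", variable), coerced,
               session$username, meta = list(participant = pid))
  if (identical(inst$status, "empty")) {
    recordChange(store, "crfs", key, "status", "in-progress",
                 session$username, meta = list(participant = pid))
    updateVisitStatus(store, defn, pid, inst$visit_id)
  }
  invisible(list(stored = TRUE, flags = flags))
}

#' Acknowledge a warn flag
#'
#' Per-flag, recorded with username and timestamp in the audit trail.
#' Block flags are never acknowledgeable.
#'
#' @param store an `edc_store`.
#' @param session acting session.
#' @param key CRF instance key.
#' @param flag_id flag identifier.
#' @export
acknowledgeFlag <- function(store, session, key, flag_id) {
  requirePrivilege(store, session, "enter-data")
  inst <- store$state$crfs[[key]]
  f <- inst$flags[[flag_id]]
  if (is.null(f)) edcStop("edc_reference_error", "no flag '%s' on '%s'", flag_id, key)
  if (identical(f$severity, "block")) {
    edcStop("edc_state_error", "block flags cannot be acknowledged")
  }
  f$acknowledged_by <- session$username
  f$acknowledged_at <- formatTs(store$clock())
  recordChange(store, "crfs", key, paste0("flags.", flag_id), f,
               session$username, meta = list(participant = inst$participant))
  invisible(flag_id)
}

ensureFlag <- function(store, key, flag, username, pid) {
  inst <- store$state$crfs[[key]]
  for (fid in names(inst$flags)) {
    f <- inst$flags[[fid]]
    if (!isTRUE(f$voided) && identical(f$kind, flag$kind) &&
        identical(f$variable, flag$variable)) {
      return(fid)
    }
  }
  addFlag(store, key, flag, username, pid)
}

#' Complete a CRF instance
#'
#' Completion requires every required or high-importance visible variable
#' to be non-blank or to carry an acknowledged blank flag, and every warn
#' flag (range, cross-field, blank) to be acknowledged. On success the
#' instance becomes `complete`, trigger rules whose source lies in this CRF
#' fire ([applyTriggers()]), and — when the CRF is a predicate CRF of any
#' eligibility criterion — eligibility is re-evaluated immediately.
#'
#' @inheritParams enterValue
#' @return invisibly, the keys of any CRF instances spawned by triggers.
#' @export
completeCrf <- function(store, defn, session, key) {
  requirePrivilege(store, session, "enter-data")
  inst <- store$state$crfs[[key]]
  if (is.null(inst)) edcStop("edc_reference_error", "unknown instance '%s'", key)
  if (identical(inst$status, "signed")) {
    edcStop("edc_state_error", "instance '%s' is already signed", key)
  }
  crf <- defn$crfs[[inst$crf_id]]
  pid <- inst$participant
  vis <- visibleVariables(defn, inst$crf_id, inst$values)

  must_fill <- Filter(function(vn) {
    vd <- crf$variables[[vn]]
    (isTRUE(vd$required) || isTRUE(vd$high_importance)) &&
      isBlankValue(inst$values[[vn]])
  }, vis)
  for (vn in must_fill) {
    ensureFlag(store, key,
               list(kind = "blank-importance", severity = "warn",
                    variable = vn,
                    message = sprintf("'%s' is blank at completion; verify", vn)),
               session$username, pid)
  }
  for (f in checkCrossField(defn, inst$crf_id, inst$values, vis)) {
    if (identical(f$kind, "cross-field")) {
      ensureFlag(store, key, f, session$username, pid)
    }
  }
  inst <- store$state$crfs[[key]]
  outstanding <- Filter(function(f) is.null(f$acknowledged_by), activeFlags(inst))
  req_blank <- Filter(function(vn) isTRUE(crf$variables[[vn]]$required),
                      must_fill)
  unacked_blank <- vapply(outstanding, function(f) {
    identical(f$kind, "blank-importance") && f$variable %in% req_blank
  }, logical(1))
  if (any(unacked_blank)) {
    edcStop("edc_completeness_error",
            "required variable(s) incomplete: %s",
            paste(unique(vapply(outstanding[unacked_blank],
                                function(f) f$variable, character(1))),
                  collapse = ", "))
  }
  if (length(outstanding) > 0) {
    edcStop("edc_flag_error",
            "%d unacknowledged flag(s) on '%s': %s",
            length(outstanding), key,
            paste(vapply(outstanding, function(f) f$message, character(1)),
                  collapse = " | "))
  }

  recordChange(store, "crfs", key, "status", "complete", session$username,
               meta = list(participant = pid))
  recordChange(store, "crfs", key, "completed_at", formatTs(store$clock()),
               session$username, meta = list(participant = pid))
  updateVisitStatus(store, defn, pid, inst$visit_id)
  spawned <- applyTriggers(store, defn, session, key)
  preds <- unique(unlist(predicateCrfs(defn)))
  if (length(defn$criteria) > 0 &&
      (inst$crf_id %in% preds || length(preds) == 0)) {
    evaluateEligibility(store, defn, pid)
  }
  invisible(spawned)
}

#' Fire trigger rules whose source lies in a completed CRF
#'
#' Count-mode rules reconcile the set of spawned instances to the source
#' value: growth creates the missing ordinals (reviving retired ones
#' first); shrink never deletes — surplus instances are retired and, when
#' they already contain data, flagged for data-manager review. Predicate
#' rules spawn exactly one instance while their condition holds. Re-running
#' with an unchanged source value is a no-op.
#'
#' @inheritParams enterValue
#' @return character vector of newly created instance keys.
#' @export
applyTriggers <- function(store, defn, session, key) {
  inst <- store$state$crfs[[key]]
  if (!inst$status %in% c("complete", "signed")) {
    edcStop("edc_state_error", "triggers fire only on completed CRFs")
  }
  pid <- inst$participant
  created <- character(0)
  for (rule in defn$triggers) {
    if (!identical(rule$source_crf, inst$crf_id)) next
    res <- evalRuleExpression(parseRuleExpression(rule$expression, "local"),
                              inst$values)
    n <- if (identical(rule$mode, "count")) {
      v <- suppressWarnings(as.integer(res))
      if (is.na(v)) 0L else v
    } else {
      if (isTRUE(res)) 1L else 0L
    }
    target_visit <- if (identical(rule$target_visit_policy, "unscheduled")) {
      createUnscheduledVisit(store, defn, session, pid)
      "unscheduled"
    } else {
      inst$visit_id
    }
    mine <- Filter(function(i) {
      identical(i$origin$kind, "triggered") &&
        identical(i$origin$rule_id, rule$rule_id) &&
        identical(i$origin$source, key)
    }, crfInstancesFor(store, pid, target_visit, rule$target_crf,
                       include_surplus = TRUE))
    ords <- vapply(mine, function(i) i$origin$rule_ordinal, integer(1))
    mine <- mine[order(ords)]
    active <- Filter(function(i) !isTRUE(i$surplus), mine)
    n_have <- length(mine)
    n_active <- length(active)
    if (n > n_active) {
      for (i in mine) {
        if (n_active >= n) break
        if (isTRUE(i$surplus)) {
          recordChange(store, "crfs", i$instance_key, "surplus", FALSE,
                       session$username, meta = list(participant = pid))
          n_active <- n_active + 1L
        }
      }
      while (n_active < n) {
        n_have <- n_have + 1L
        k <- createCrfInstance(store, defn, pid, target_visit, rule$target_crf,
                               list(kind = "triggered", rule_id = rule$rule_id,
                                    rule_ordinal = n_have, source = key),
                               session$username)
        created <- c(created, k)
        n_active <- n_active + 1L
      }
    } else if (n < n_active) {
      excess <- rev(active)[seq_len(n_active - n)]
      for (i in excess) {
        recordChange(store, "crfs", i$instance_key, "surplus", TRUE,
                     session$username, meta = list(participant = pid))
        if (length(i$values) > 0) {
          ensureFlag(store, i$instance_key,
                     list(kind = "surplus-review", severity = "warn",
                          variable = NULL,
                          message = sprintf(
                            "instance retired by trigger reconciliation (rule '%s') but contains data; data-manager review required",
                            rule$rule_id)),
                     session$username, pid)
        }
      }
    }
    updateVisitStatus(store, defn, pid, target_visit)
  }
  created
}

#' Consent CRFs required for a participant's age
#'
#' The routing rule whose half-open age band `[min, max)` in completed
#' years contains the participant's age determines the set; partial or
#' stated birth dates resolve by the youngest-possible convention
#' ([computeAge()]).
#'
#' @param store an `edc_store`.
#' @param defn compiled study definition.
#' @param pid participant id.
#' @param as_of reference date (defaults to the store clock's today).
#' @return character vector of consent crf_ids.
#' @export
requiredConsentForms <- function(store, defn, pid,
                                 as_of = as.Date(store$clock())) {
  if (length(defn$consent_routing) == 0) return(character(0))
  age <- participantAge(store, pid, as_of)$years
  for (band in defn$consent_routing) {
    hi <- band$age_max %||% Inf
    if (age >= band$age_min && age < hi) {
      return(as.character(unlist(band$consent_crfs)))
    }
  }
  edcStop("edc_routing_error",
          "no consent routing band covers age %d (participant '%s')", age, pid)
}

consentSatisfied <- function(store, defn, pid) {
  if (length(defn$consent_routing) == 0) return(TRUE)
  routed <- tryCatch(requiredConsentForms(store, defn, pid),
                     error = function(e) NULL)
  if (is.null(routed)) return(FALSE)
  blocking <- Filter(function(b) isTRUE(b$blocks_progression), defn$consent_routing)
  blocking_crfs <- intersect(routed,
                             unlist(lapply(blocking, function(b) unlist(b$consent_crfs))))
  for (cid in blocking_crfs) {
    insts <- crfInstancesFor(store, pid, crf_id = cid)
    if (length(insts) == 0 ||
        !any(vapply(insts, function(i) identical(i$status, "signed"), logical(1)))) {
      return(FALSE)
    }
  }
  TRUE
}

#' CRFs a participant may currently progress to
#'
#' Enforces the protocol so the wrong form can never be filled out: only
#' CRFs whose prerequisites hold are returned. Pre-consent CRFs
#' (recruitment/screening forms marked `pre_consent`) and the consent CRFs
#' routed for the participant's age band are available first; everything
#' else opens only once the routed blocking consent forms are signed and
#' the participant is eligible. An ineligible participant is limited to
#' pre-consent CRFs. Visits open in order: a visit's CRFs are available
#' only when every earlier scheduled visit is complete.
#'
#' @param store an `edc_store`.
#' @param defn compiled study definition.
#' @param pid participant id.
#' @return sorted character vector of currently permitted crf_ids.
#' @export
gateProgression <- function(store, defn, pid) {
  p <- store$state$participants[[pid]]
  if (is.null(p)) edcStop("edc_reference_error", "unknown participant '%s'", pid)
  elig <- store$state$eligibility[[pid]]$overall %||%
    (if (length(defn$criteria) == 0) "eligible" else "pending")
  consent_ids <- names(Filter(function(cf) isTRUE(cf$is_consent_form), defn$crfs))
  pre_ids <- names(Filter(function(cf) isTRUE(cf$pre_consent), defn$crfs))
  routed <- tryCatch(requiredConsentForms(store, defn, pid),
                     error = function(e) character(0))

  if (identical(elig, "ineligible") || p$status %in% c("withdrawn", "completed")) {
    return(sort(setdiff(pre_ids, consent_ids)))
  }

  ## visit window: scheduled visits open in order
  open_visits <- character(0)
  for (vid in unlist(defn$visit_order)) {
    open_visits <- c(open_visits, vid)
    if (!identical(visitStatus(store, defn, pid, vid), "complete")) break
  }
  unsched <- vapply(store$state$visits, function(v) {
    identical(v$participant, pid) &&
      !(v$visit_id %in% unlist(defn$visit_order))
  }, logical(1))
  open_visits <- c(open_visits,
                   vapply(store$state$visits[unsched],
                          function(v) v$visit_id, character(1)))

  consent_ok <- consentSatisfied(store, defn, pid)
  preds <- unique(unlist(predicateCrfs(defn)))
  permitted <- character(0)
  for (inst in crfInstancesFor(store, pid)) {
    if (!inst$visit_id %in% open_visits) next
    cid <- inst$crf_id
    if (cid %in% consent_ids) {
      if (cid %in% routed) permitted <- c(permitted, cid)
    } else if (cid %in% pre_ids) {
      permitted <- c(permitted, cid)
    } else if (consent_ok &&
               (identical(elig, "eligible") || cid %in% preds)) {
      ## predicate (screening) CRFs stay open while eligibility is pending —
      ## they are what decides it
      permitted <- c(permitted, cid)
    }
  }
  sort(unique(permitted))
}

#' Sign a completed CRF instance
#'
#' Signing re-verifies credentials at the moment of signature. The signer's
#' role must carry the signing privilege and each signature slot must be
#' filled by a distinct person; once the configured number of slots is
#' filled the instance locks (`signed`) and only the audited data-manager
#' edit path can change it.
#'
#' @param store an `edc_store`.
#' @param defn compiled study definition.
#' @param key CRF instance key.
#' @param username,password signing credentials.
#' @return invisibly, the instance status after signing.
#' @export
signCrf <- function(store, defn, key, username, password) {
  inst <- store$state$crfs[[key]]
  if (is.null(inst)) edcStop("edc_reference_error", "unknown instance '%s'", key)
  if (!identical(inst$status, "complete")) {
    edcStop("edc_state_error",
            "instance '%s' is %s; only complete CRFs can be signed",
            key, inst$status)
  }
  session <- authenticate(store, username, password)
  requirePrivilege(store, session, "sign")
  signers <- vapply(inst$signatures, function(s) s$username, character(1))
  if (username %in% signers) {
    edcStop("edc_state_error",
            "'%s' already occupies a signature slot on '%s'; slots require distinct personnel",
            username, key)
  }
  sig <- list(username = username, role = session$role,
              signed_at = formatTs(store$clock()), credential_verified = TRUE)
  recordChange(store, "crfs", key, "signatures",
               c(inst$signatures, list(sig)), username,
               meta = list(participant = inst$participant))
  slots <- defn$crfs[[inst$crf_id]]$signature_slots
  newst <- inst$status
  if (length(inst$signatures) + 1L >= slots) {
    newst <- "signed"
    recordChange(store, "crfs", key, "status", "signed", username,
                 meta = list(participant = inst$participant))
    updateVisitStatus(store, defn, inst$participant, inst$visit_id)
  }
  invisible(newst)
}

#' Audited edit of a signed CRF (data-manager path)
#'
#' The only way to change a signed instance. Requires the `edit-signed`
#' privilege; the change is written to the audit trail with an edit marker,
#' all signatures are voided (the form must be re-signed), and — when the
#' edited variable feeds an eligibility criterion — eligibility is
#' re-evaluated in full, which may flip a terminal state (itself audited).
#'
#' @inheritParams enterValue
#' @export
editSignedValue <- function(store, defn, session, key, variable, value) {
  requirePrivilege(store, session, "edit-signed")
  inst <- store$state$crfs[[key]]
  if (is.null(inst)) edcStop("edc_reference_error", "unknown instance '%s'", key)
  crf <- defn$crfs[[inst$crf_id]]
  vardef <- crf$variables[[variable]]
  if (is.null(vardef)) {
    edcStop("edc_reference_error", "no variable '%s' in crf '%s'",
            variable, inst$crf_id)
  }
  coerced <- coerceValue(vardef, value)
  flags <- checkValue(vardef, coerced)
  if (any(vapply(flags, function(f) f$severity, character(1)) == "block")) {
    edcStop("edc_flag_error", "edit rejected: %s", flags[[1]]$message)
  }
  pid <- inst$participant
  recordChange(store, "crfs", key, paste0("values.", variable), coerced,
               session$username,
               meta = list(participant = pid, edit_signed = TRUE))
  if (length(inst$signatures) > 0) {
    recordChange(store, "crfs", key, "signatures", list(), session$username,
                 meta = list(participant = pid, edit_signed = TRUE))
  }
  if (identical(inst$status, "signed")) {
    recordChange(store, "crfs", key, "status", "complete", session$username,
                 meta = list(participant = pid, edit_signed = TRUE))
    updateVisitStatus(store, defn, pid, inst$visit_id)
  }
  qv <- paste(inst$crf_id, variable, sep = ".")
  crit_vars <- unlist(lapply(defn$criteria, function(k) {
    parseRuleExpression(k$expression, "qualified")$vars
  }))
  if (qv %in% crit_vars) {
    evaluateEligibility(store, defn, pid, force = TRUE)
  }
  invisible(key)
}
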