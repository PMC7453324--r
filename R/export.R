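## Flat-file export (one table per CRF type) and external-results import.

choiceLabel <- function(vardef, code, language) {
  if (isBlankValue(code)) return(NA_character_)
  labs <- character(0)
  for (part in splitList(gsub(";", ";", as.character(code)))) {
    hit <- Filter(function(ch) identical(ch$code, part), vardef$choices)
    labs <- c(labs, if (length(hit) > 0) {
      hit[[1]]$label[[language]] %||% hit[[1]]$label[[1]]
    } else part)
  }
  paste(labs, collapse = ";")
}

exportValue <- function(x) {
  if (isBlankValue(x)) return(NA_character_)
  as.character(x)
}

#' Export the store as flat tables, one file per CRF type
#'
#' Mirrors the downstream-analysis workflow: one CSV per CRF type (one row
#' per instance, linkage keys first, variables in dictionary order, choice
#' variables as code plus label columns), plus `participants`,
#' `households` and — because it reveals the arm — the role-gated
#' `allocations` table. Repeated exports of the same store are
#' byte-identical. With `deidentify = TRUE` every variable flagged
#' identifying, and the participants' name fields, are dropped.
#'
#' @param store an `edc_store`.
#' @param defn compiled study definition.
#' @param session session with `export` privilege.
#' @param dir output directory (created if needed).
#' @param deidentify drop identifying columns.
#' @param language language for label columns.
#' @param crfs CRF ids to export (default all).
#' @param include_audit also write `audit.csv` (the change log).
#' @return named character vector of written file paths.
#' @export
exportTables <- function(store, defn, session, dir, deidentify = FALSE,
                         language = defn$default_language, crfs = NULL,
                         include_audit = FALSE) {
  requirePrivilege(store, session, "export")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  crfs <- crfs %||% names(defn$crfs)
  unknown <- setdiff(crfs, names(defn$crfs))
  if (length(unknown) > 0) {
    edcStop("edc_reference_error", "unknown CRF(s) in export spec: %s",
            paste(unknown, collapse = ", "))
  }
  files <- character(0)
  writeStable <- function(df, name) {
    path <- file.path(dir, paste0(name, ".csv"))
    con <- file(path, open = "wb")
    on.exit(close(con))
    utils::write.csv(df, con, row.names = FALSE, na = "", eol = "\n",
                     fileEncoding = "UTF-8")
    files[[name]] <<- path
  }

  for (cid in crfs) {
    crf <- defn$crfs[[cid]]
    vars <- crf$var_order
    if (deidentify) {
      vars <- Filter(function(vn) !isTRUE(crf$variables[[vn]]$identifying), vars)
    }
    insts <- Filter(function(i) identical(i$crf_id, cid),
                    store$state$crfs)
    ord <- order(vapply(insts, function(i) {
      sprintf("%s|%03d|%s", i$participant,
              match(i$visit_id, unlist(defn$visit_order), nomatch = 999L),
              formatC(i$ordinal, width = 3, flag = "0"))
    }, character(1)))
    insts <- insts[ord]
    rows <- lapply(insts, function(i) {
      p <- store$state$participants[[i$participant]]
      row <- list(personal_id = i$participant,
                  household_id = exportValue(p$household_id),
                  visit_id = i$visit_id,
                  ordinal = i$ordinal,
                  origin = i$origin$kind)
      for (vn in vars) {
        vd <- crf$variables[[vn]]
        row[[vn]] <- exportValue(i$values[[vn]])
        if (vd$type %in% c("choice", "multi-choice")) {
          row[[paste0(vn, "_label")]] <-
            if (isBlankValue(i$values[[vn]])) NA_character_ else
              choiceLabel(vd, i$values[[vn]], language)
        }
      }
      row$status <- i$status
      row$created_at <- i$created_at
      row$completed_at <- exportValue(i$completed_at)
      row$schema_version <- i$schema_version
      as.data.frame(row, stringsAsFactors = FALSE)
    })
    df <- if (length(rows) > 0) do.call(rbind, rows) else {
      template <- c("personal_id", "household_id", "visit_id", "ordinal",
                    "origin", vars, "status", "created_at", "completed_at",
                    "schema_version")
      as.data.frame(stats::setNames(rep(list(character(0)), length(template)),
                                    template), stringsAsFactors = FALSE)
    }
    writeStable(df, cid)
  }

  pids <- sort(names(store$state$participants))
  prow <- lapply(pids, function(pid) {
    p <- store$state$participants[[pid]]
    row <- list(personal_id = pid,
                household_id = exportValue(p$household_id),
                enrollment_id = exportValue(p$enrollment_id),
                status = p$status,
                dob_kind = p$dob$kind,
                registered_at = p$registered_at,
                device_code = p$device_code)
    if (!deidentify) {
      for (nf in names(p$name_fields)) row[[nf]] <- exportValue(p$name_fields[[nf]])
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  writeStable(if (length(prow) > 0) do.call(rbind, prow) else
    data.frame(personal_id = character(0)), "participants")

  hids <- sort(names(store$state$households))
  hrow <- lapply(hids, function(hid) {
    h <- store$state$households[[hid]]
    data.frame(household_id = hid, device_code = h$device_code,
               stringsAsFactors = FALSE)
  })
  writeStable(if (length(hrow) > 0) do.call(rbind, hrow) else
    data.frame(household_id = character(0)), "households")

  aids <- sort(names(store$state$allocations))
  arow <- lapply(aids, function(pid) {
    a <- store$state$allocations[[pid]]
    data.frame(personal_id = pid, sequence_no = a$sequence_no,
               color_group = a$color_group, arm = a$arm,
               midline_visit = exportValue(a$midline_visit),
               allocated_at = a$allocated_at, stringsAsFactors = FALSE)
  })
  writeStable(if (length(arow) > 0) do.call(rbind, arow) else
    data.frame(personal_id = character(0)), "allocations")

  if (include_audit) {
    audit <- lapply(store$log, function(r) {
      data.frame(change_id = r$change_id, device = r$device,
                 entity = r$entity, key = r$key, field = r$field,
                 old = exportValue(if (is.list(r$old)) "<record>" else r$old),
                 new = exportValue(if (is.list(r$new)) "<record>" else r$new),
                 username = r$username, logical_ts = r$logical_ts,
                 wall_ts = r$wall_ts, stringsAsFactors = FALSE)
    })
    writeStable(if (length(audit) > 0) do.call(rbind, audit) else
      data.frame(change_id = character(0)), "audit")
  }
  files
}

#' Import externally computed results as CRF instances
#'
#' Lab results or externally analyzed eligibility inputs re-enter the
#' store through the normal validation path: each file row becomes a
#' sequence of value entries on a fresh instance of `crf_id`, with
#' identical range flags to interactive entry (a soft-range value is
#' stored with its warn flag left pending acknowledgment). Rows whose
#' `personal_id` is unknown are rejected and reported, never skipped
#' silently.
#'
#' @param store an `edc_store`.
#' @param defn compiled study definition.
#' @param session session with `enter-data` privilege.
#' @param file CSV path (or data frame) with a `personal_id` column plus
#'   columns named after the CRF's variables.
#' @param crf_id the target CRF.
#' @param visit_id target visit; defaults to an on-demand unscheduled
#'   visit.
#' @return report data frame: one row per input row with `personal_id`,
#'   `accepted`, `instance_key`, `status`, `reason`.
#' @export
importExternalResults <- function(store, defn, session, file, crf_id,
                                  visit_id = "unscheduled") {
  requirePrivilege(store, session, "enter-data")
  if (is.null(defn$crfs[[crf_id]])) {
    edcStop("edc_reference_error", "unknown crf '%s'", crf_id)
  }
  df <- if (is.data.frame(file)) file else {
    utils::read.csv(file, colClasses = "character", na.strings = character(0))
  }
  if (!"personal_id" %in% names(df)) {
    edcStop("edc_reference_error", "import file needs a personal_id column")
  }
  vars <- intersect(names(df), defn$crfs[[crf_id]]$var_order)
  report <- list()
  for (i in seq_len(nrow(df))) {
    pid <- df$personal_id[[i]]
    if (is.null(store$state$participants[[pid]])) {
      report[[i]] <- data.frame(personal_id = pid, accepted = FALSE,
                                instance_key = NA_character_,
                                status = NA_character_,
                                reason = "unknown participant id",
                                stringsAsFactors = FALSE)
      next
    }
    if (!visit_id %in% unlist(defn$visit_order)) {
      createUnscheduledVisit(store, defn, session, pid, visit_id)
    }
    key <- createCrfInstance(store, defn, pid, visit_id, crf_id,
                             list(kind = "scheduled"), session$username)
    for (vn in vars) {
      val <- df[[vn]][[i]]
      if (isBlankValue(val)) next
      res <- enterValue(store, defn, session, key, vn, val)
      if (!res$stored &&
          all(vapply(res$flags, function(f) f$severity, character(1)) == "warn")) {
        ## imports keep the value; the warn flag stays pending acknowledgment
        vd <- defn$crfs[[crf_id]]$variables[[vn]]
        recordChange(store, "crfs", key, paste0("values.", vn),
                     coerceValue(vd, val), session$username,
                     meta = list(participant = pid, import = TRUE))
      }
    }
    status <- tryCatch({
      completeCrf(store, defn, session, key)
      "complete"
    }, edc_error = function(e) "in-progress")
    report[[i]] <- data.frame(personal_id = pid, accepted = TRUE,
                              instance_key = key, status = status,
                              reason = "", stringsAsFactors = FALSE)
  }
  do.call(rbind, report)
}
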