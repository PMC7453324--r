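#' Load and compile a study workbook into an immutable StudyDefinition
#'
#' A study is declared entirely as data, in a workbook of tabular sheets.
#' The canonical dialect is a directory of CSV files (one per sheet); an
#' XLSX workbook with the same sheet names is accepted when the readxl
#' package is installed. Sheets:
#'
#' * `dictionary` — one row per variable: `crf_id, name, type, label_<lang>,
#'   choices` (`code=label|code=label`), `soft_low, soft_high, hard_low,
#'   hard_high, required, high_importance, identifying, unit, skip_if`.
#' * `forms` — CRF-level attributes: `crf_id, title_<lang>, signature_slots,
#'   is_consent_form, consent_class, pre_consent`.
#' * `visits` — `visit_id, label, order_index, scheduled`.
#' * `schedule` — the visit-by-CRF matrix in long form: `visit_id, crf_id,
#'   mode` with mode in `always | midline | trigger`.
#' * `criteria` — `criterion_id, expression, description`; expressions use
#'   qualified `crf.variable` references (see [parseRuleExpression()]).
#' * `triggers` — `rule_id, source_crf, expression, mode (count|predicate),
#'   target_crf, target_visit_policy (same-visit|unscheduled)`.
#' * `consent` — age-routing bands in completed years, half-open
#'   `[age_min, age_max)`: `band_id, age_min, age_max, consent_crfs,
#'   blocks_progression` (blank `age_max` = unbounded).
#' * `ids` — identifier scheme components: `scope (participant|household),
#'   position, component (study-code|device-code|sequential|group-letter),
#'   value` (fixed text for study-code, digit width otherwise).
#' * `validation` — cross-field, replicate and adaptive rules (see
#'   [checkCrossField()], [replicateGate()], [adaptiveInstruction()]).
#' * `randomization_config` — `color_group, arm` mapping rows plus an
#'   optional `midline_sampling` column.
#' * `study` — `study_code, version, default_language, sync_cadence`.
#'
#' `dictionary`, `forms`, `visits` and `schedule` are required; all other
#' sheets may be absent (an empty criteria sheet yields an all-pass
#' eligibility rule set). Compilation cross-checks every reference and
#' reports *all* offenders in one error. Loading is deterministic: the same
#' workbook always compiles to a byte-identical serialization
#' (see [writeStudyDefinition()]).
#'
#' @param path directory of CSV sheets, an `.xlsx` file, or a named list of
#'   data frames keyed by sheet name.
#' @return an immutable `edc_study_definition` (a locked nested list).
#' @export
loadStudyDefinition <- function(path) {
  sheets <- readWorkbookSheets(path)
  required <- c("dictionary", "forms", "visits", "schedule")
  missing <- setdiff(required, names(sheets))
  if (length(missing) > 0) {
    edcStop("edc_schema_missing_error",
            "workbook is missing required sheet(s): %s",
            paste(missing, collapse = ", "))
  }
  problems <- character(0)
  note <- function(...) problems[[length(problems) + 1L]] <<- sprintf(...)

  meta <- sheetRows(sheets[["study"]])
  study_code <- if (length(meta) > 0) meta[[1]]$study_code %||% "STUDY" else "STUDY"
  version <- if (length(meta) > 0) {
    as.integer(asNumericOrNA(meta[[1]]$version) %||% 1)
  } else 1L
  if (is.na(version)) version <- 1L
  default_language <- if (length(meta) > 0) {
    meta[[1]]$default_language %||% "en"
  } else "en"
  sync_cadence <- if (length(meta) > 0) meta[[1]]$sync_cadence %||% "daily" else "daily"

  ## ---- forms + dictionary -> CRF definitions --------------------------
  forms <- sheetRows(sheets[["forms"]])
  dict <- sheetRows(sheets[["dictionary"]])
  languages <- unique(c(
    default_language,
    sub("^label_", "", grep("^label_", names(sheets[["dictionary"]]), value = TRUE)),
    sub("^title_", "", grep("^title_", names(sheets[["forms"]]), value = TRUE))
  ))

  crf_ids <- vapply(forms, function(r) r$crf_id %||% "", character(1))
  if (anyDuplicated(crf_ids)) {
    note("duplicate crf_id in forms sheet: %s",
         paste(unique(crf_ids[duplicated(crf_ids)]), collapse = ", "))
  }
  crfs <- list()
  for (r in forms) {
    cid <- r$crf_id
    if (isBlankValue(cid)) { note("forms row with blank crf_id"); next }
    slots <- as.integer(asNumericOrNA(r$signature_slots))
    if (is.na(slots)) slots <- 1L
    if (slots < 1) note("crf '%s': signature_slots must be >= 1", cid)
    cclass <- r$consent_class
    if (isBlankValue(cclass)) cclass <- NULL
    crfs[[cid]] <- list(
      crf_id = cid,
      title = langMap(r, "title_", default_language),
      signature_slots = slots,
      is_consent_form = asLogicalFlag(r$is_consent_form),
      consent_class = cclass,
      pre_consent = asLogicalFlag(r$pre_consent),
      variables = list(),
      var_order = character(0)
    )
  }

  valid_types <- c("integer", "decimal", "text", "date", "choice",
                   "multi-choice", "signature-ref", "attachment-ref")
  for (r in dict) {
    cid <- r$crf_id; nm <- r$name
    if (isBlankValue(cid) || is.null(crfs[[cid]])) {
      note("dictionary row for unknown crf '%s' (variable '%s')",
           cid %||% "?", nm %||% "?")
      next
    }
    if (isBlankValue(nm)) { note("dictionary row in '%s' with blank name", cid); next }
    if (nm %in% crfs[[cid]]$var_order) {
      note("duplicate variable '%s' in crf '%s'", nm, cid)
      next
    }
    type <- r$type %||% "text"
    if (!type %in% valid_types) {
      note("variable '%s.%s': unknown type '%s'", cid, nm, type)
    }
    choices <- parseChoices(r, default_language)
    if (type %in% c("choice", "multi-choice") && length(choices) == 0) {
      note("choice variable '%s.%s' declares no choices", cid, nm)
    }
    if (!type %in% c("choice", "multi-choice") && length(choices) > 0) {
      note("non-choice variable '%s.%s' declares choices", cid, nm)
    }
    soft <- rangeOrNull(r$soft_low, r$soft_high)
    hard <- rangeOrNull(r$hard_low, r$hard_high)
    if (!is.null(soft) && !is.null(hard) &&
        (soft[[1]] < hard[[1]] || soft[[2]] > hard[[2]])) {
      note("variable '%s.%s': soft range not contained in hard range", cid, nm)
    }
    skip_if <- r$skip_if
    if (isBlankValue(skip_if)) skip_if <- NULL
    if (!is.null(skip_if)) {
      parsed <- tryCatch(parseRuleExpression(skip_if, "local"),
                         error = function(e) { note("%s", conditionMessage(e)); NULL })
      if (!is.null(parsed)) {
        earlier <- crfs[[cid]]$var_order
        bad <- setdiff(parsed$vars, earlier)
        if (length(bad) > 0) {
          note("skip rule on '%s.%s' references variable(s) not defined earlier: %s",
               cid, nm, paste(bad, collapse = ", "))
        }
      }
    }
    unit <- r$unit; if (isBlankValue(unit)) unit <- NULL
    crfs[[cid]]$variables[[nm]] <- list(
      name = nm,
      type = type,
      label = langMap(r, "label_", default_language),
      choices = if (length(choices) > 0) choices else NULL,
      soft_range = soft,
      hard_range = hard,
      required = asLogicalFlag(r$required),
      high_importance = asLogicalFlag(r$high_importance),
      identifying = asLogicalFlag(r$identifying),
      unit = unit,
      skip_if = skip_if
    )
    crfs[[cid]]$var_order <- c(crfs[[cid]]$var_order, nm)
  }

  ## ---- visits ----------------------------------------------------------
  visits <- list()
  for (r in sheetRows(sheets[["visits"]])) {
    vid <- r$visit_id
    if (isBlankValue(vid)) { note("visits row with blank visit_id"); next }
    if (!is.null(visits[[vid]])) { note("duplicate visit_id '%s'", vid); next }
    visits[[vid]] <- list(
      visit_id = vid,
      label = r$label %||% vid,
      order_index = as.integer(asNumericOrNA(r$order_index)),
      scheduled = asLogicalFlag(r$scheduled, default = TRUE)
    )
  }
  sched_orders <- vapply(visits, function(v) {
    if (isTRUE(v$scheduled)) v$order_index else NA_integer_
  }, integer(1))
  if (anyDuplicated(stats::na.omit(sched_orders))) {
    note("duplicate order_index among scheduled visits")
  }
  visit_order <- names(sort(sched_orders[!is.na(sched_orders)]))

  ## ---- schedule --------------------------------------------------------
  schedule <- list()
  seen_cells <- character(0)
  for (r in sheetRows(sheets[["schedule"]])) {
    vid <- r$visit_id; cid <- r$crf_id
    mode <- r$mode %||% "always"
    if (!mode %in% c("always", "midline", "trigger")) {
      note("schedule cell (%s, %s): unknown mode '%s'", vid, cid, mode)
    }
    if (is.null(visits[[vid %||% ""]])) note("schedule references unknown visit '%s'", vid %||% "?")
    if (is.null(crfs[[cid %||% ""]])) note("schedule references unknown crf '%s'", cid %||% "?")
    key <- paste(vid, cid, sep = "\r")
    if (key %in% seen_cells) {
      note("schedule cell (%s, %s) appears more than once", vid, cid)
      next
    }
    seen_cells <- c(seen_cells, key)
    schedule[[length(schedule) + 1L]] <- list(visit_id = vid, crf_id = cid, mode = mode)
  }

  ## ---- criteria --------------------------------------------------------
  criteria <- list()
  for (r in sheetRows(sheets[["criteria"]])) {
    kid <- r$criterion_id
    if (isBlankValue(kid)) { note("criteria row with blank criterion_id"); next }
    if (!is.null(criteria[[kid]])) { note("duplicate criterion_id '%s'", kid); next }
    parsed <- tryCatch(parseRuleExpression(r$expression, "qualified"),
                       error = function(e) { note("criterion '%s': %s", kid, conditionMessage(e)); NULL })
    if (!is.null(parsed)) {
      for (v in parsed$vars) {
        parts <- strsplit(v, ".", fixed = TRUE)[[1]]
        if (parts[[1]] == "participant") {
          if (!parts[[2]] %in% c("age_years", "age_precision")) {
            note("criterion '%s' references unknown builtin '%s'", kid, v)
          }
        } else if (is.null(crfs[[parts[[1]]]])) {
          note("criterion '%s' references unknown crf '%s'", kid, parts[[1]])
        } else if (is.null(crfs[[parts[[1]]]]$variables[[parts[[2]]]])) {
          note("criterion '%s' references unknown variable '%s'", kid, v)
        }
      }
    }
    criteria[[kid]] <- list(
      criterion_id = kid,
      expression = r$expression,
      description = r$description %||% ""
    )
  }

  ## ---- triggers --------------------------------------------------------
  triggers <- list()
  for (r in sheetRows(sheets[["triggers"]])) {
    rid <- r$rule_id
    if (isBlankValue(rid)) { note("triggers row with blank rule_id"); next }
    if (!is.null(triggers[[rid]])) { note("duplicate rule_id '%s'", rid); next }
    src <- r$source_crf
    mode <- r$mode %||% "predicate"
    if (!mode %in% c("count", "predicate")) note("trigger '%s': unknown mode '%s'", rid, mode)
    if (is.null(crfs[[src %||% ""]])) {
      note("trigger '%s' has unknown source crf '%s'", rid, src %||% "?")
    } else {
      parsed <- tryCatch(parseRuleExpression(r$expression, "local"),
                         error = function(e) { note("trigger '%s': %s", rid, conditionMessage(e)); NULL })
      if (!is.null(parsed)) {
        bad <- setdiff(parsed$vars, crfs[[src]]$var_order)
        if (length(bad) > 0) {
          note("trigger '%s' references unknown variable(s) %s in crf '%s'",
               rid, paste(bad, collapse = ", "), src)
        }
        if (mode == "count") {
          if (length(parsed$vars) != 1 || !is.name(parsed$expr)) {
            note("count-mode trigger '%s' must name a single integer variable", rid)
          } else {
            vt <- crfs[[src]]$variables[[parsed$vars]]$type
            if (!identical(vt, "integer")) {
              note("count-mode trigger '%s': source '%s' is %s, not integer",
                   rid, parsed$vars, vt %||% "unknown")
            }
          }
        }
      }
    }
    if (is.null(crfs[[r$target_crf %||% ""]])) {
      note("trigger '%s' has unknown target crf '%s'", rid, r$target_crf %||% "?")
    }
    policy <- r$target_visit_policy %||% "same-visit"
    if (!policy %in% c("same-visit", "unscheduled")) {
      note("trigger '%s': unknown target_visit_policy '%s'", rid, policy)
    }
    triggers[[rid]] <- list(
      rule_id = rid, source_crf = src, expression = r$expression,
      mode = mode, target_crf = r$target_crf, target_visit_policy = policy
    )
  }

  ## ---- consent routing -------------------------------------------------
  consent_routing <- list()
  for (r in sheetRows(sheets[["consent"]])) {
    lo <- asNumericOrNA(r$age_min); hi <- asNumericOrNA(r$age_max)
    if (is.na(lo)) { note("consent band '%s' has no age_min", r$band_id %||% "?"); next }
    cids <- splitList(r$consent_crfs)
    for (cc in cids) {
      if (is.null(crfs[[cc]])) {
        note("consent band '%s' routes to unknown crf '%s'", r$band_id %||% "?", cc)
      } else if (!isTRUE(crfs[[cc]]$is_consent_form)) {
        note("consent band '%s' routes to non-consent crf '%s'", r$band_id %||% "?", cc)
      }
    }
    consent_routing[[length(consent_routing) + 1L]] <- list(
      band_id = r$band_id %||% sprintf("band%d", length(consent_routing) + 1L),
      age_min = lo,
      age_max = if (is.na(hi)) NULL else hi,
      consent_crfs = as.list(cids),
      blocks_progression = asLogicalFlag(r$blocks_progression, default = TRUE)
    )
  }
  if (length(consent_routing) > 1) {
    for (i in seq_along(consent_routing)) {
      for (j in seq_along(consent_routing)) {
        if (i >= j) next
        a <- consent_routing[[i]]; b <- consent_routing[[j]]
        amax <- a$age_max %||% Inf; bmax <- b$age_max %||% Inf
        if (a$age_min < bmax && b$age_min < amax) {
          note("consent bands '%s' and '%s' overlap", a$band_id, b$band_id)
        }
      }
    }
  }

  ## ---- id scheme -------------------------------------------------------
  id_scheme <- list(participant = NULL, household = NULL)
  ids_rows <- sheetRows(sheets[["ids"]])
  for (scope in c("participant", "household")) {
    rows <- Filter(function(r) identical(r$scope %||% "participant", scope), ids_rows)
    if (length(rows) == 0) next
    pos <- order(vapply(rows, function(r) asNumericOrNA(r$position) %||% NA_real_, numeric(1)))
    comps <- list()
    for (r in rows[pos]) {
      comp <- r$component
      if (!comp %in% c("study-code", "device-code", "sequential", "group-letter")) {
        note("ids: unknown component '%s'", comp %||% "?")
        next
      }
      entry <- list(component = comp)
      if (comp == "study-code") {
        entry$value <- r$value %||% study_code
      } else if (comp %in% c("device-code", "sequential")) {
        w <- as.integer(asNumericOrNA(r$value))
        if (is.na(w) || w < 1) {
          note("ids: %s component needs a digit width >= 1", comp)
          w <- 4L
        }
        entry$width <- w
      }
      comps[[length(comps) + 1L]] <- entry
    }
    nseq <- sum(vapply(comps, function(cp) cp$component == "sequential", logical(1)))
    if (nseq != 1) note("ids: scope '%s' must have exactly one sequential component", scope)
    id_scheme[[scope]] <- comps
  }
  if (is.null(id_scheme$participant)) {
    id_scheme$participant <- list(list(component = "sequential", width = 4L))
  }

  ## ---- randomization config -------------------------------------------
  randomization <- NULL
  rc <- sheetRows(sheets[["randomization_config"]])
  if (length(rc) > 0) {
    color_to_arm <- list()
    midline <- FALSE
    for (r in rc) {
      cg <- r$color_group
      if (isBlankValue(cg)) next
      if (!is.null(color_to_arm[[cg]])) note("duplicate color_group '%s'", cg)
      color_to_arm[[cg]] <- r$arm %||% ""
      if (!is.null(r$midline_sampling)) {
        midline <- midline || asLogicalFlag(r$midline_sampling)
      }
    }
    randomization <- list(
      color_to_arm = color_to_arm,
      arms = as.list(sort(unique(unlist(color_to_arm)))),
      midline_sampling = midline
    )
  }
  has_letter <- any(vapply(id_scheme$participant,
                           function(cp) cp$component == "group-letter", logical(1)))
  if (has_letter && is.null(randomization)) {
    note("id scheme has a group-letter component but no randomization_config sheet")
  }

  ## ---- validation rules ------------------------------------------------
  vr <- list(cross_field = list(), replicates = list(), adaptive = list())
  for (r in sheetRows(sheets[["validation"]])) {
    kind <- r$kind %||% ""
    cid <- r$crf_id %||% ""
    if (is.null(crfs[[cid]])) {
      note("validation rule '%s' on unknown crf '%s'", r$rule_id %||% "?", cid)
      next
    }
    if (kind == "cross-field") {
      parsed <- tryCatch(parseRuleExpression(r$expression, "local"),
                         error = function(e) { note("rule '%s': %s", r$rule_id %||% "?", conditionMessage(e)); NULL })
      vars <- if (!is.null(parsed)) parsed$vars else splitList(r$variables)
      if (length(vars) < 2) {
        note("cross-field rule '%s' must reference >= 2 variables", r$rule_id %||% "?")
      }
      bad <- setdiff(vars, crfs[[cid]]$var_order)
      if (length(bad) > 0) {
        note("cross-field rule '%s' references unknown variable(s): %s",
             r$rule_id %||% "?", paste(bad, collapse = ", "))
      }
      vr$cross_field[[length(vr$cross_field) + 1L]] <- list(
        rule_id = r$rule_id, crf_id = cid, expression = r$expression,
        variables = as.list(vars),
        message = langMap(r, "message_", default_language)
      )
    } else if (kind == "replicate") {
      n_base <- as.integer(asNumericOrNA(r$n_base))
      n_extra <- as.integer(asNumericOrNA(r$n_extra) %||% 1)
      if (is.na(n_extra)) n_extra <- 1L
      thr <- asNumericOrNA(r$threshold)
      if (is.na(n_base) || n_base < 2) note("replicate rule '%s': n_base must be >= 2", r$rule_id %||% "?")
      if (is.na(thr) || thr <= 0) note("replicate rule '%s': threshold must be > 0", r$rule_id %||% "?")
      stem <- r$stem %||% ""
      expect <- paste0(stem, "_r", seq_len(max(n_base, 0L, na.rm = TRUE) + n_extra))
      bad <- setdiff(expect, crfs[[cid]]$var_order)
      if (length(bad) > 0) {
        note("replicate rule '%s': missing replicate field(s) %s in crf '%s'",
             r$rule_id %||% "?", paste(bad, collapse = ", "), cid)
      }
      vr$replicates[[length(vr$replicates) + 1L]] <- list(
        rule_id = r$rule_id, crf_id = cid, stem = stem,
        n_base = n_base, n_extra = n_extra,
        threshold = thr,
        threshold_type = r$threshold_type %||% "absolute"
      )
    } else if (kind == "adaptive") {
      det <- r$determinant %||% ""
      aff <- splitList(r$affected)
      bad <- setdiff(c(det, aff), crfs[[cid]]$var_order)
      if (length(bad) > 0) {
        note("adaptive rule '%s': unknown variable(s) %s", r$rule_id %||% "?",
             paste(bad, collapse = ", "))
      }
      vr$adaptive[[length(vr$adaptive) + 1L]] <- list(
        rule_id = r$rule_id, crf_id = cid, determinant = det,
        instruction = langMap(r, "instruction_", default_language),
        affected = as.list(aff)
      )
    } else {
      note("validation rule '%s': unknown kind '%s'", r$rule_id %||% "?", kind)
    }
  }

  if (length(problems) > 0) {
    edcStop("edc_reference_error",
            "study definition failed to compile:\n- %s",
            paste(problems, collapse = "\n- "))
  }

  defn <- list(
    study_code = study_code,
    version = version,
    languages = as.list(languages),
    default_language = default_language,
    sync_cadence = sync_cadence,
    crfs = crfs,
    visits = visits,
    visit_order = as.list(visit_order),
    schedule = schedule,
    criteria = criteria,
    triggers = triggers,
    consent_routing = consent_routing,
    id_scheme = id_scheme,
    randomization = randomization,
    validation_rules = vr
  )
  class(defn) <- "edc_study_definition"
  defn
}

## ---- sheet plumbing ----------------------------------------------------

readWorkbookSheets <- function(path) {
  sheet_names <- c("study", "forms", "dictionary", "visits", "schedule",
                   "criteria", "triggers", "consent", "ids", "validation",
                   "randomization_config")
  if (is.list(path) && !is.null(names(path))) {
    return(lapply(path, function(d) as.data.frame(lapply(d, as.character),
                                                  check.names = FALSE,
                                                  stringsAsFactors = FALSE)))
  }
  if (length(path) == 1 && grepl("\\.xlsx$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      edcStop("edc_schema_missing_error",
              "reading XLSX workbooks requires the readxl package; use the CSV dialect")
    }
    present <- intersect(sheet_names, readxl::excel_sheets(path))
    out <- lapply(present, function(s) {
      d <- readxl::read_excel(path, sheet = s, col_types = "text")
      as.data.frame(d, check.names = FALSE, stringsAsFactors = FALSE)
    })
    names(out) <- present
    return(out)
  }
  if (!dir.exists(path)) {
    edcStop("edc_schema_missing_error", "workbook path '%s' does not exist", path)
  }
  files <- list.files(path, pattern = "\\.csv$", full.names = TRUE)
  present <- intersect(sheet_names, sub("\\.csv$", "", basename(files)))
  out <- lapply(present, function(s) {
    utils::read.csv(file.path(path, paste0(s, ".csv")),
                    colClasses = "character", check.names = FALSE,
                    na.strings = character(0), fileEncoding = "UTF-8")
  })
  names(out) <- present
  out
}

sheetRows <- function(df) {
  if (is.null(df) || nrow(df) == 0) return(list())
  lapply(seq_len(nrow(df)), function(i) {
    row <- as.list(df[i, , drop = FALSE])
    row <- lapply(row, function(x) {
      x <- as.character(x)
      if (length(x) == 0 || is.na(x) || !nzchar(trimws(x))) NULL else trimws(x)
    })
    Filter(Negate(is.null), row)
  })
}

langMap <- function(row, prefix, default_language) {
  keys <- grep(paste0("^", prefix), names(row), value = TRUE)
  out <- list()
  for (k in keys) {
    lang <- sub(paste0("^", prefix), "", k)
    if (!isBlankValue(row[[k]])) out[[lang]] <- row[[k]]
  }
  if (length(out) == 0) out[[default_language]] <- ""
  out
}

parseChoices <- function(row, default_language) {
  raw <- row$choices
  if (isBlankValue(raw)) return(list())
  parts <- strsplit(raw, "|", fixed = TRUE)[[1]]
  extra_langs <- grep("^choices_", names(row), value = TRUE)
  out <- list()
  for (i in seq_along(parts)) {
    kv <- strsplit(parts[[i]], "=", fixed = TRUE)[[1]]
    code <- trimws(kv[[1]])
    lab <- list()
    lab[[default_language]] <- if (length(kv) > 1) trimws(paste(kv[-1], collapse = "=")) else code
    for (cl in extra_langs) {
      lang <- sub("^choices_", "", cl)
      lparts <- strsplit(row[[cl]] %||% "", "|", fixed = TRUE)[[1]]
      if (length(lparts) >= i) {
        lkv <- strsplit(lparts[[i]], "=", fixed = TRUE)[[1]]
        if (length(lkv) > 1) lab[[lang]] <- trimws(paste(lkv[-1], collapse = "="))
      }
    }
    out[[length(out) + 1L]] <- list(code = code, label = lab)
  }
  out
}

rangeOrNull <- function(lo, hi) {
  lo <- asNumericOrNA(lo); hi <- asNumericOrNA(hi)
  if (is.na(lo) && is.na(hi)) return(NULL)
  list(low = if (is.na(lo)) NULL else lo, high = if (is.na(hi)) NULL else hi)
}

## ---- queries over a compiled definition --------------------------------

#' Map each eligibility criterion to its predicate CRFs
#'
#' A criterion's predicate CRFs are the CRFs whose variables its expression
#' reads; eligibility is re-evaluated whenever one of them completes.
#' References to the `participant` pseudo-CRF (registry-derived values such
#' as age) are not predicate CRFs — they are available from registration.
#'
#' @param defn a compiled study definition.
#' @return named list: criterion_id -> character vector of crf_ids.
#' @export
predicateCrfs <- function(defn) {
  stopifnot(inherits(defn, "edc_study_definition"))
  out <- list()
  for (kid in names(defn$criteria)) {
    parsed <- parseRuleExpression(defn$criteria[[kid]]$expression, "qualified")
    out[[kid]] <- exprCrfRefs(parsed)
  }
  out
}

#' Lint a compiled study definition
#'
#' Linting reports protocol-design smells that compilation does not reject:
#' unreachable CRFs (in no schedule cell and targeted by no trigger),
#' consent CRFs outside every routing band, gaps between consecutive consent
#' age bands (including an assent/parental form with no band below 18),
#' criterion/trigger/cross-field variables that are neither required nor
#' high-importance (a protocol-critical field that may legally stay blank),
#' and missing translations for declared languages.
#'
#' @param defn a compiled study definition.
#' @return character vector of diagnostics; `character(0)` when clean.
#' @export
lintStudyDefinition <- function(defn) {
  stopifnot(inherits(defn, "edc_study_definition"))
  diags <- character(0)
  say <- function(...) diags[[length(diags) + 1L]] <<- sprintf(...)

  scheduled_crfs <- unique(vapply(defn$schedule, function(c) c$crf_id, character(1)))
  trigger_targets <- unique(vapply(defn$triggers, function(t) t$target_crf, character(1)))
  for (cid in names(defn$crfs)) {
    if (!cid %in% c(scheduled_crfs, trigger_targets)) {
      say("unreachable CRF '%s': not in any schedule cell and not a trigger target", cid)
    }
  }

  routed <- unique(unlist(lapply(defn$consent_routing, function(b) unlist(b$consent_crfs))))
  for (cid in names(defn$crfs)) {
    if (isTRUE(defn$crfs[[cid]]$is_consent_form) && !cid %in% routed) {
      say("consent CRF '%s' is outside every consent routing rule", cid)
    }
  }

  if (length(defn$consent_routing) > 0) {
    bands <- defn$consent_routing
    mins <- vapply(bands, function(b) b$age_min, numeric(1))
    bands <- bands[order(mins)]
    for (i in seq_along(bands)[-1]) {
      prev_max <- bands[[i - 1]]$age_max %||% Inf
      if (bands[[i]]$age_min > prev_max) {
        say("consent routing gap: ages [%s, %s) are covered by no band",
            format(prev_max), format(bands[[i]]$age_min))
      }
    }
    minor_classes <- c("adolescent-assent", "parental-consent")
    has_minor_form <- any(vapply(defn$crfs, function(cf) {
      isTRUE(cf$is_consent_form) && (cf$consent_class %||% "") %in% minor_classes
    }, logical(1)))
    covers_minor <- any(vapply(defn$consent_routing,
                               function(b) b$age_min < 18, logical(1)))
    if (has_minor_form && !covers_minor) {
      say("consent routing gap: assent/parental-consent CRF present but no band covers ages < 18")
    }
  }

  rule_vars <- character(0)
  for (k in names(defn$criteria)) {
    rule_vars <- c(rule_vars,
                   parseRuleExpression(defn$criteria[[k]]$expression, "qualified")$vars)
  }
  for (t in defn$triggers) {
    p <- parseRuleExpression(t$expression, "local")
    rule_vars <- c(rule_vars, paste(t$source_crf, p$vars, sep = "."))
  }
  for (r in defn$validation_rules$cross_field) {
    rule_vars <- c(rule_vars, paste(r$crf_id, unlist(r$variables), sep = "."))
  }
  for (cid in names(defn$crfs)) {
    for (vn in defn$crfs[[cid]]$var_order) {
      vd <- defn$crfs[[cid]]$variables[[vn]]
      if (!is.null(vd$skip_if)) {
        p <- parseRuleExpression(vd$skip_if, "local")
        rule_vars <- c(rule_vars, paste(cid, p$vars, sep = "."))
      }
    }
  }
  for (qv in setdiff(unique(rule_vars), grep("^participant\\.", rule_vars, value = TRUE))) {
    parts <- strsplit(qv, ".", fixed = TRUE)[[1]]
    vd <- defn$crfs[[parts[[1]]]]$variables[[parts[[2]]]]
    if (!is.null(vd) && !isTRUE(vd$required) && !isTRUE(vd$high_importance)) {
      say("variable '%s' drives a rule but is neither required nor high-importance", qv)
    }
  }

  for (lang in unlist(defn$languages)) {
    for (cid in names(defn$crfs)) {
      cf <- defn$crfs[[cid]]
      if (is.null(cf$title[[lang]])) {
        say("missing %s title for CRF '%s'", lang, cid)
      }
      for (vn in cf$var_order) {
        if (is.null(cf$variables[[vn]]$label[[lang]])) {
          say("missing %s label for variable '%s.%s'", lang, cid, vn)
        }
      }
    }
  }
  diags
}

#' @export
print.edc_study_definition <- function(x, ...) {
  cat(sprintf("<edc_study_definition> %s (v%d)\n", x$study_code, x$version))
  cat(sprintf("  CRFs: %d | scheduled visits: %d | criteria: %d | triggers: %d\n",
              length(x$crfs), length(x$visit_order),
              length(x$criteria), length(x$triggers)))
  cat(sprintf("  consent bands: %d | languages: %s\n",
              length(x$consent_routing),
              paste(unlist(x$languages), collapse = ", ")))
  if (!is.null(x$randomization)) {
    cat(sprintf("  randomization: %d color group(s) -> %d arm(s)%s\n",
                length(x$randomization$color_to_arm),
                length(x$randomization$arms),
                if (isTRUE(x$randomization$midline_sampling)) " + midline sampling" else ""))
  }
  invisible(x)
}

## ---- serialization -----------------------------------------------------

#' Serialize / restore a compiled study definition
#'
#' The canonical serialization is JSON with stable key order, suitable for
#' deploying one compiled protocol to many capture devices. Round-tripping
#' is byte-stable: `writeStudyDefinition(readStudyDefinition(p))` reproduces
#' `p` exactly.
#'
#' @param defn a compiled study definition.
#' @param path file path; for `writeStudyDefinition` omit to get the JSON
#'   string back instead of writing a file.
#' @return `writeStudyDefinition`: the JSON string, invisibly when written
#'   to a file. `readStudyDefinition`: an `edc_study_definition`.
#' @export
writeStudyDefinition <- function(defn, path = NULL) {
  stopifnot(inherits(defn, "edc_study_definition"))
  x <- unclass(defn)
  for (cid in names(x$crfs)) {
    x$crfs[[cid]]$var_order <- as.list(x$crfs[[cid]]$var_order)
  }
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, null = "null",
                           digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(json))
  writeLines(as.character(json), path, useBytes = TRUE)
  invisible(as.character(json))
}

#' @rdname writeStudyDefinition
#' @export
readStudyDefinition <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  defn <- canonicalizeDefinition(raw)
  class(defn) <- "edc_study_definition"
  defn
}

canonicalizeDefinition <- function(x) {
  x$version <- as.integer(x$version)
  for (cid in names(x$crfs)) {
    x$crfs[[cid]]$signature_slots <- as.integer(x$crfs[[cid]]$signature_slots)
    x$crfs[[cid]]$var_order <- as.character(unlist(x$crfs[[cid]]$var_order))
  }
  for (vid in names(x$visits)) {
    x$visits[[vid]]$order_index <- as.integer(x$visits[[vid]]$order_index)
  }
  for (s in c("participant", "household")) {
    if (!is.null(x$id_scheme[[s]])) {
      x$id_scheme[[s]] <- lapply(x$id_scheme[[s]], function(cp) {
        if (!is.null(cp$width)) cp$width <- as.integer(cp$width)
        cp
      })
    }
  }
  x$validation_rules$replicates <- lapply(x$validation_rules$replicates, function(r) {
    r$n_base <- as.integer(r$n_base); r$n_extra <- as.integer(r$n_extra)
    r
  })
  x
}
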