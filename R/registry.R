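#' Date-of-birth information of varying precision
#'
#' Field registration rarely has a verified birth certificate. Three kinds of
#' information are supported: an exact date, a partial date (year with
#' optional month), and a stated age as of a reference date. Downstream age
#' computation resolves the ambiguity conservatively (see [computeAge()]).
#'
#' @param date,year,month,age_years,as_of components of the respective kind.
#' @return an object of class `edc_dob`.
#' @export
dobExact <- function(date) {
  d <- as.Date(date)
  if (is.na(d)) edcStop("edc_domain_error", "invalid exact date of birth")
  structure(list(kind = "exact-date", date = as.character(d)), class = "edc_dob")
}

#' @rdname dobExact
#' @export
dobPartial <- function(year, month = NULL) {
  year <- as.integer(year)
  if (is.na(year) || year < 1000 || year > 9999) {
    edcStop("edc_domain_error", "partial date of birth needs a plausible 4-digit year")
  }
  if (!is.null(month)) {
    month <- as.integer(month)
    if (is.na(month) || month < 1 || month > 12) {
      edcStop("edc_domain_error", "partial date of birth month must be 1..12")
    }
  }
  structure(list(kind = "partial-date", year = year, month = month),
            class = "edc_dob")
}

#' @rdname dobExact
#' @export
dobStated <- function(age_years, as_of) {
  age_years <- as.integer(age_years)
  as_of <- as.Date(as_of)
  if (is.na(age_years) || age_years < 0 || is.na(as_of)) {
    edcStop("edc_domain_error", "stated age needs a non-negative age and an as-of date")
  }
  structure(list(kind = "stated-age", age_years = age_years,
                 as_of = as.character(as_of)),
            class = "edc_dob")
}

#' Compute a participant's age from heterogeneous date-of-birth information
#'
#' Consent routing and age-banded eligibility need the participant's age in
#' completed years (to the day where derivable) in real time, from whatever
#' birth-date information is available:
#'
#' * exact date: age to the day, precision `"exact"`;
#' * partial date: the *youngest possible* age consistent with the known
#'   year (and month), i.e. computed from the latest consistent birth date,
#'   precision `"estimated"` — the conservative direction, so an ambiguous
#'   17/18-year-old is routed to assent + parental consent, never
#'   prematurely to adult consent;
#' * stated age: the stated value plus completed years elapsed since its
#'   as-of date, precision `"stated"`.
#'
#' Ages are non-decreasing in `as_of` for every kind, and the anniversary
#' day itself counts as completing the year.
#'
#' @param dob an `edc_dob` (see [dobExact()]).
#' @param as_of reference date.
#' @return list with `years` (integer completed years), `days` (integer,
#'   `NA` unless exact), and `precision` (`"exact"`, `"estimated"`,
#'   `"stated"`).
#' @export
computeAge <- function(dob, as_of) {
  stopifnot(inherits(dob, "edc_dob"))
  as_of <- as.Date(as_of)
  if (is.na(as_of)) edcStop("edc_domain_error", "invalid as_of date")
  if (dob$kind == "exact-date") {
    bd <- as.Date(dob$date)
    if (bd > as_of) edcStop("edc_domain_error", "birth date lies in the future")
    return(list(years = completedYears(bd, as_of),
                days = as.integer(as_of - bd),
                precision = "exact"))
  }
  if (dob$kind == "partial-date") {
    latest <- if (is.null(dob$month)) {
      as.Date(sprintf("%d-12-31", dob$year))
    } else {
      lastDayOfMonth(dob$year, dob$month)
    }
    earliest <- if (is.null(dob$month)) {
      as.Date(sprintf("%d-01-01", dob$year))
    } else {
      as.Date(sprintf("%d-%02d-01", dob$year, dob$month))
    }
    if (earliest > as_of) edcStop("edc_domain_error", "birth year lies in the future")
    latest <- min(latest, as_of)
    return(list(years = completedYears(latest, as_of),
                days = NA_integer_,
                precision = "estimated"))
  }
  ref <- as.Date(dob$as_of)
  if (ref > as_of) edcStop("edc_domain_error", "stated-age reference date lies in the future")
  list(years = dob$age_years + completedYears(ref, as_of),
       days = NA_integer_,
       precision = "stated")
}

## ---- component-structured identifiers ----------------------------------

idSchemeHasGroupLetter <- function(scheme) {
  any(vapply(scheme, function(cp) cp$component == "group-letter", logical(1)))
}

#' Generate a component-structured participant identifier
#'
#' Identifiers are the in-order concatenation of the scheme's components:
#' a fixed study code, the capture device's code (zero-padded to the
#' configured width), a zero-padded per-device sequential counter, and —
#' for randomized designs — the allocation's color-group letter. Because
#' the sequential counter is scoped to the device and the device code is
#' embedded in the identifier, devices generate collision-free identifiers
#' with no server coordination.
#'
#' @param defn compiled study definition (supplies the scheme and study code).
#' @param device_code code of the capturing device.
#' @param seq_no the device's sequential counter value for this identifier.
#' @param allocation an allocation (for the group-letter component), or
#'   `NULL`. Required iff the scheme has a group-letter component, unless
#'   `partial = TRUE`.
#' @param partial if `TRUE`, omit the group-letter component (used for the
#'   provisional registration identifier before allocation).
#' @param scope `"participant"` or `"household"`.
#' @return the identifier string.
#' @export
generateParticipantId <- function(defn, device_code, seq_no, allocation = NULL,
                                  partial = FALSE, scope = "participant") {
  scheme <- defn$id_scheme[[scope]]
  if (is.null(scheme)) edcStop("edc_definition_error", "no id scheme for scope '%s'", scope)
  out <- character(0)
  for (cp in scheme) {
    if (cp$component == "study-code") {
      out <- c(out, cp$value)
    } else if (cp$component == "device-code") {
      dc <- as.character(device_code)
      if (nchar(dc) > cp$width) {
        edcStop("edc_capacity_error", "device code '%s' exceeds width %d", dc, cp$width)
      }
      out <- c(out, formatC(dc, width = cp$width, flag = "0"))
    } else if (cp$component == "sequential") {
      if (seq_no > 10^cp$width - 1) {
        edcStop("edc_capacity_error",
                "sequential counter %d exhausts the %d-digit id component",
                seq_no, cp$width)
      }
      out <- c(out, formatC(as.integer(seq_no), width = cp$width, flag = "0"))
    } else if (cp$component == "group-letter") {
      if (partial) next
      if (is.null(allocation)) {
        edcStop("edc_ordering_error",
                "id scheme has a group-letter component but no allocation was supplied")
      }
      out <- c(out, as.character(allocation$color_group))
    }
  }
  paste(out, collapse = "")
}

#' Parse an identifier back into its scheme components
#'
#' @param defn compiled study definition.
#' @param id identifier produced by [generateParticipantId()].
#' @param partial whether the id was generated without its group-letter
#'   component.
#' @inheritParams generateParticipantId
#' @return named list of component values.
#' @export
parseParticipantId <- function(defn, id, partial = FALSE, scope = "participant") {
  scheme <- defn$id_scheme[[scope]]
  pos <- 1L
  out <- list()
  for (cp in scheme) {
    w <- switch(cp$component,
                "study-code" = nchar(cp$value),
                "device-code" = cp$width,
                "sequential" = cp$width,
                "group-letter" = if (partial) 0L else 1L)
    if (w == 0L) next
    piece <- substr(id, pos, pos + w - 1L)
    if (nchar(piece) < w) {
      edcStop("edc_domain_error", "id '%s' is too short for the scheme", id)
    }
    out[[cp$component]] <- piece
    pos <- pos + w
  }
  if (pos != nchar(id) + 1L) {
    edcStop("edc_domain_error", "id '%s' has trailing characters beyond the scheme", id)
  }
  if (!is.null(out[["study-code"]])) {
    sc <- vapply(scheme, function(cp) identical(cp$component, "study-code"), logical(1))
    expected <- scheme[[which(sc)[1]]]$value
    if (!identical(out[["study-code"]], expected)) {
      edcStop("edc_domain_error", "id '%s' carries study code '%s', expected '%s'",
              id, out[["study-code"]], expected)
    }
  }
  if (!is.null(out[["sequential"]])) {
    out[["sequential"]] <- as.integer(out[["sequential"]])
  }
  out
}

.participantStatuses <- c("registered", "screening", "eligible", "ineligible",
                          "enrolled", "withdrawn", "completed")

## Allowed lifecycle transitions; withdrawn and (post-decision) ineligible
## are terminal absent an audited correction.
.statusTransitions <- list(
  registered = c("screening", "eligible", "ineligible", "withdrawn"),
  screening  = c("eligible", "ineligible", "withdrawn"),
  eligible   = c("enrolled", "withdrawn"),
  ineligible = character(0),
  enrolled   = c("withdrawn", "completed"),
  withdrawn  = character(0),
  completed  = character(0)
)

statusTransitionAllowed <- function(from, to) {
  to %in% (.statusTransitions[[from]] %||% character(0))
}
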