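`%||%` <- function(x, y) if (is.null(x)) y else x

#' Stop with a classed condition
#'
#' All engine errors carry a condition class (`edc_*_error`) so callers and
#' tests can distinguish, e.g., permission errors from validation errors.
#' @noRd
edcStop <- function(class, fmt, ...) {
  msg <- if (length(list(...)) > 0) sprintf(fmt, ...) else fmt
  stop(structure(
    class = c(class, "edc_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

isBlankValue <- function(x) {
  is.null(x) || length(x) == 0 ||
    (length(x) == 1 && (is.na(x) || (is.character(x) && !nzchar(x))))
}

asLogicalFlag <- function(x, default = FALSE) {
  if (isBlankValue(x)) return(default)
  if (is.logical(x)) return(isTRUE(x))
  tolower(as.character(x)) %in% c("1", "true", "yes", "y")
}

asNumericOrNA <- function(x) {
  if (isBlankValue(x)) return(NA_real_)
  suppressWarnings(as.numeric(x))
}

#' Split a semicolon-separated cell into a character vector
#' @noRd
splitList <- function(x) {
  if (isBlankValue(x)) return(character(0))
  out <- trimws(strsplit(as.character(x), ";", fixed = TRUE)[[1]])
  out[nzchar(out)]
}

#' ISO timestamp formatting used everywhere a wall-clock time is stored.
#' A fixed format keeps serialized stores and exports byte-stable.
#' @noRd
formatTs <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

#' Completed years between two dates (the anniversary day itself counts as
#' completed).
#' @noRd
completedYears <- function(from, to) {
  from <- as.Date(from); to <- as.Date(to)
  if (is.na(from) || is.na(to)) return(NA_integer_)
  fy <- as.integer(format(from, "%Y")); ty <- as.integer(format(to, "%Y"))
  fm <- as.integer(format(from, "%m")); tm <- as.integer(format(to, "%m"))
  fd <- as.integer(format(from, "%d")); td <- as.integer(format(to, "%d"))
  y <- ty - fy
  if (tm < fm || (tm == fm && td < fd)) y <- y - 1L
  as.integer(y)
}

lastDayOfMonth <- function(year, month) {
  first_next <- if (month == 12) {
    as.Date(sprintf("%d-01-01", year + 1))
  } else {
    as.Date(sprintf("%d-%02d-01", year, month + 1))
  }
  first_next - 1
}
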