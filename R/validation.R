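#' Real-time value validation against plausibility and possibility bounds
#'
#' Two bands per numeric variable: the *hard* range bounds what is possible
#' at all (exclusive endpoints — a negative or zero body weight is
#' impossible) and violating it raises a `block` flag that prevents storage;
#' the *soft* range bounds what is plausible (inclusive endpoints) and
#' violating it raises a `warn` flag that the enumerator must acknowledge
#' before the value is kept. A value inside both bands raises nothing.
#'
#' @param vardef a variable definition from a compiled study definition.
#' @param value the candidate value (numeric variables only are range-checked).
#' @return list of flags, each `list(kind, severity, variable, message)`;
#'   empty when the value is acceptable.
#' @export
checkValue <- function(vardef, value) {
  flags <- list()
  if (!vardef$type %in% c("integer", "decimal")) return(flags)
  v <- asNumericOrNA(value)
  if (is.na(v)) return(flags)
  hr <- vardef$hard_range
  if (!is.null(hr)) {
    lo <- hr$low %||% -Inf; hi <- hr$high %||% Inf
    if (v <= lo || v >= hi) {
      return(list(list(kind = "hard-range", severity = "block",
                       variable = vardef$name,
                       message = sprintf("%s = %s is impossible (allowed %s..%s, exclusive)",
                                         vardef$name, format(v), format(lo), format(hi)))))
    }
  }
  sr <- vardef$soft_range
  if (!is.null(sr)) {
    lo <- sr$low %||% -Inf; hi <- sr$high %||% Inf
    if (v < lo || v > hi) {
      flags[[1]] <- list(kind = "soft-range", severity = "warn",
                         variable = vardef$name,
                         message = sprintf("%s = %s is outside the anticipated range [%s, %s]",
                                           vardef$name, format(v), format(lo), format(hi)))
    }
  }
  flags
}

#' Cross-field contradiction and blank-importance checks
#'
#' Cross-field rules state a *contradiction condition* over two or more
#' variables of one CRF (e.g. never-pregnant with a positive pregnancy
#' count); when the condition evaluates `TRUE` on the current values, one
#' `warn` flag naming all involved variables is raised. Additionally, every
#' high-importance variable left blank yields a blank-importance `warn`
#' flag requiring verification.
#'
#' @param defn compiled study definition.
#' @param crf_id the CRF being checked.
#' @param values named list of current values for that CRF.
#' @param visible_vars variables currently visible (hidden variables are
#'   exempt from blank-importance checks); defaults to all.
#' @return list of flags as in [checkValue()].
#' @export
checkCrossField <- function(defn, crf_id, values, visible_vars = NULL) {
  flags <- list()
  crf <- defn$crfs[[crf_id]]
  if (is.null(visible_vars)) visible_vars <- crf$var_order
  for (rule in defn$validation_rules$cross_field) {
    if (!identical(rule$crf_id, crf_id)) next
    res <- evalRuleExpression(parseRuleExpression(rule$expression, "local"), values)
    if (isTRUE(res)) {
      flags[[length(flags) + 1L]] <- list(
        kind = "cross-field", severity = "warn",
        variable = paste(unlist(rule$variables), collapse = ","),
        rule_id = rule$rule_id,
        message = rule$message[[defn$default_language]] %||%
          sprintf("contradictory entries across %s",
                  paste(unlist(rule$variables), collapse = ", "))
      )
    }
  }
  for (vn in intersect(crf$var_order, visible_vars)) {
    vd <- crf$variables[[vn]]
    if (isTRUE(vd$high_importance) && isBlankValue(values[[vn]])) {
      flags[[length(flags) + 1L]] <- list(
        kind = "blank-importance", severity = "warn", variable = vn,
        message = sprintf("high-importance variable '%s' is blank; verify before continuing", vn)
      )
    }
  }
  flags
}

#' Replicate variation
#'
#' Absolute metric: maximum pairwise absolute difference. Relative metric:
#' the same maximum divided by the replicate mean.
#' @noRd
replicateVariation <- function(vals, type = "absolute") {
  vals <- vals[!is.na(vals)]
  if (length(vals) < 2) return(0)
  spread <- max(vals) - min(vals)
  if (identical(type, "relative")) spread / mean(vals) else spread
}

#' Sequential replicate gating with a variation threshold
#'
#' Replicate fields are revealed strictly in sequence — replicate *k + 1*
#' becomes visible only once replicate *k* is entered — forcing a full
#' re-measurement protocol rather than repeated reads in one position. When
#' all base replicates are in and their variation exceeds the threshold,
#' the extra replicate fields are revealed (also sequentially).
#'
#' @param spec a replicate rule (`stem`, `n_base`, `n_extra`, `threshold`,
#'   `threshold_type`) from a compiled definition.
#' @param values named list of current CRF values.
#' @return character vector of replicate variable names currently visible.
#' @export
replicateGate <- function(spec, values) {
  fields <- paste0(spec$stem, "_r", seq_len(spec$n_base + spec$n_extra))
  visible <- fields[[1]]
  for (k in seq_len(spec$n_base - 1L)) {
    if (isBlankValue(values[[fields[[k]]]])) return(visible)
    visible <- c(visible, fields[[k + 1L]])
  }
  base_vals <- vapply(fields[seq_len(spec$n_base)],
                      function(f) asNumericOrNA(values[[f]]), numeric(1))
  if (any(is.na(base_vals))) return(visible)
  if (replicateVariation(base_vals, spec$threshold_type) <= spec$threshold) {
    return(visible)
  }
  for (j in seq_len(spec$n_extra)) {
    f <- fields[[spec$n_base + j]]
    visible <- c(visible, f)
    if (isBlankValue(values[[f]])) break
  }
  visible
}

#' Adaptive measurement instruction
#'
#' Renders the rule's instruction with the complement of the determinant
#' substituted for `{side}` (dominant right arm -> measure the LEFT,
#' nondominant arm). While the determinant is blank the affected variables
#' stay locked and no instruction is produced.
#'
#' @param rule an adaptive rule from a compiled definition.
#' @param values named list of current CRF values.
#' @param language language code for the instruction text.
#' @return the rendered instruction, or `NULL` while the determinant is
#'   unanswered.
#' @export
adaptiveInstruction <- function(rule, values, language = NULL) {
  det <- values[[rule$determinant]]
  if (isBlankValue(det)) return(NULL)
  complement <- c(left = "right", right = "left")[[tolower(as.character(det))]] %||% NA
  if (is.na(complement)) {
    edcStop("edc_definition_error",
            "adaptive determinant value '%s' has no complement", det)
  }
  template <- if (!is.null(language)) {
    rule$instruction[[language]] %||% rule$instruction[[1]]
  } else {
    rule$instruction[[1]]
  }
  gsub("{side}", toupper(complement), template, fixed = TRUE)
}

#' Variables of a CRF currently visible for data entry
#'
#' Combines the three visibility mechanisms: skip rules (hide when the
#' condition is `TRUE` on earlier answers), sequential replicate gating,
#' and adaptive locks (affected variables hidden until the determinant is
#' answered).
#'
#' @param defn compiled study definition.
#' @param crf_id CRF identifier.
#' @param values named list of current values.
#' @return character vector of visible variable names, in dictionary order.
#' @export
visibleVariables <- function(defn, crf_id, values) {
  crf <- defn$crfs[[crf_id]]
  visible <- character(0)
  replicate_fields <- character(0)
  replicate_visible <- character(0)
  for (spec in defn$validation_rules$replicates) {
    if (!identical(spec$crf_id, crf_id)) next
    replicate_fields <- c(replicate_fields,
                          paste0(spec$stem, "_r", seq_len(spec$n_base + spec$n_extra)))
    replicate_visible <- c(replicate_visible, replicateGate(spec, values))
  }
  locked <- character(0)
  for (rule in defn$validation_rules$adaptive) {
    if (!identical(rule$crf_id, crf_id)) next
    if (isBlankValue(values[[rule$determinant]])) {
      locked <- c(locked, unlist(rule$affected))
    }
  }
  for (vn in crf$var_order) {
    vd <- crf$variables[[vn]]
    if (!is.null(vd$skip_if)) {
      hide <- evalRuleExpression(parseRuleExpression(vd$skip_if, "local"), values)
      if (isTRUE(hide)) next
    }
    if (vn %in% replicate_fields && !vn %in% replicate_visible) next
    if (vn %in% locked) next
    visible <- c(visible, vn)
  }
  visible
}
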