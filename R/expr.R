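#' Criterion / rule expression language
#'
#' Eligibility criteria, skip rules, trigger sources and cross-field checks
#' share one small, side-effect-free expression grammar: comparison and
#' arithmetic operators, the Kleene connectives `&`, `|`, `!`, `%in%`,
#' literal numbers/strings, and two helpers — `is_blank(x)` and
#' `age_years_asof(dob, date)`. Variables are referenced as
#' `crf_id.variable_name` (criteria) or bare `variable_name` (CRF-local
#' rules); the pseudo-CRF `participant` exposes registry-derived values such
#' as `participant.age_years`.
#'
#' Expressions are evaluated under three-valued logic: a variable whose CRF
#' is not yet complete (or a genuinely blank value) evaluates to `NA`, and
#' R's native Kleene semantics for `&`/`|`/`!` propagate the unknown. A
#' criterion can therefore fail (`FALSE`) before every predicate CRF exists,
#' which is what permits immediate exclusion on a single negative criterion.
#'
#' @name edc-expressions
NULL

.edcAllowedCalls <- c(
  "(", "+", "-", "*", "/", "^", "%%", "%in%",
  "<", "<=", ">", ">=", "==", "!=", "&", "|", "!",
  "c", "is_blank", "age_years_asof"
)

#' Parse a rule expression and statically list the variables it reads
#'
#' @param text expression source, e.g. `"screening.age_years >= 15 &
#'   screening.age_years <= 40"`.
#' @param context `"qualified"` (criteria: every variable must be
#'   `crf.variable`) or `"local"` (CRF-scoped rules: bare names allowed).
#' @return an object of class `edc_expr` with elements `text`, `expr`
#'   (the parsed language object) and `vars` (character vector of referenced
#'   variable names, qualified where given).
#' @export
parseRuleExpression <- function(text, context = c("qualified", "local")) {
  context <- match.arg(context)
  if (isBlankValue(text)) {
    edcStop("edc_expression_error", "empty expression")
  }
  expr <- tryCatch(str2lang(text), error = function(e) {
    edcStop("edc_expression_error", "cannot parse expression '%s': %s",
            text, conditionMessage(e))
  })
  vars <- character(0)
  walk <- function(e) {
    if (is.name(e)) {
      nm <- as.character(e)
      if (nm %in% c("T", "F")) {
        edcStop("edc_expression_error",
                "use TRUE/FALSE, not T/F, in '%s'", text)
      }
      if (!nm %in% c("TRUE", "FALSE", "NA")) {
        vars[[length(vars) + 1L]] <<- nm
      }
    } else if (is.call(e)) {
      head <- e[[1]]
      if (!is.name(head) || !(as.character(head) %in% .edcAllowedCalls)) {
        edcStop("edc_expression_error",
                "function '%s' is not allowed in rule expressions",
                deparse(head))
      }
      for (i in seq_along(e)[-1]) if (!is.null(e[[i]])) walk(e[[i]])
    }
    invisible(NULL)
  }
  walk(expr)
  vars <- unique(vars)
  if (context == "qualified") {
    bare <- vars[!grepl(".", vars, fixed = TRUE)]
    if (length(bare) > 0) {
      edcStop("edc_expression_error",
              "unqualified variable(s) %s in criterion '%s'; use crf.variable",
              paste(bare, collapse = ", "), text)
    }
  }
  structure(list(text = text, expr = expr, vars = vars),
            class = "edc_expr")
}

#' Evaluate a parsed rule expression under three-valued logic
#'
#' @param parsed an `edc_expr` from [parseRuleExpression()].
#' @param values named list mapping variable names (as referenced) to values;
#'   variables absent from the list evaluate as `NA` (unknown).
#' @return `TRUE`, `FALSE`, or `NA` (unknown) for boolean expressions;
#'   numeric results are returned as-is for count-mode triggers.
#' @export
evalRuleExpression <- function(parsed, values = list()) {
  stopifnot(inherits(parsed, "edc_expr"))
  fns <- new.env(parent = baseenv())
  assign("is_blank", function(x) isBlankValue(x), envir = fns)
  assign("age_years_asof", function(dob, asof) {
    if (isBlankValue(dob) || isBlankValue(asof)) return(NA_integer_)
    completedYears(as.Date(as.character(dob)), as.Date(as.character(asof)))
  }, envir = fns)
  env <- new.env(parent = fns)
  for (v in parsed$vars) {
    val <- values[[v]]
    if (isBlankValue(val)) val <- NA
    assign(v, val, envir = env)
  }
  out <- tryCatch(eval(parsed$expr, envir = env),
                  error = function(e) {
                    edcStop("edc_definition_error",
                            "evaluating '%s' failed: %s",
                            parsed$text, conditionMessage(e))
                  })
  if (length(out) != 1) {
    edcStop("edc_definition_error",
            "expression '%s' did not evaluate to a scalar", parsed$text)
  }
  out
}

#' CRFs read by a parsed qualified expression
#' @noRd
exprCrfRefs <- function(parsed) {
  qual <- parsed$vars[grepl(".", parsed$vars, fixed = TRUE)]
  crfs <- unique(vapply(strsplit(qual, ".", fixed = TRUE),
                        function(p) p[[1]], character(1)))
  setdiff(crfs, "participant")
}
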