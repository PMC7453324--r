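## Real-time eligibility: exclusion on a single negative criterion, inclusion
## only on completion of all predicate CRFs.

#' Values a participant's eligibility criteria can read
#'
#' Qualified variables resolve against *completed* CRF instances only; a
#' variable on an incomplete CRF is unknown (`NA`). When several completed
#' instances of one CRF exist, the structurally first (earliest scheduled
#' visit, lowest ordinal) provides the value, so the result does not depend
#' on the order in which forms happened to be completed. The `participant`
#' pseudo-CRF supplies registry-derived values (`participant.age_years`,
#' `participant.age_precision`).
#' @noRd
eligibilityValues <- function(store, defn, pid) {
  values <- list()
  age <- tryCatch(participantAge(store, pid), error = function(e) NULL)
  if (!is.null(age)) {
    values[["participant.age_years"]] <- age$years
    values[["participant.age_precision"]] <- age$precision
  }
  visit_rank <- stats::setNames(seq_along(unlist(defn$visit_order)),
                                unlist(defn$visit_order))
  insts <- crfInstancesFor(store, pid)
  done <- Filter(function(i) i$status %in% c("complete", "signed"), insts)
  if (length(done) > 0) {
    rank <- vapply(done, function(i) {
      vr <- if (i$visit_id %in% names(visit_rank)) {
        visit_rank[[i$visit_id]]
      } else 999  # unscheduled visits rank after all scheduled ones
      vr * 1000 + i$ordinal
    }, numeric(1))
    done <- done[order(rank)]
    for (inst in done) {
      for (vn in names(inst$values)) {
        qv <- paste(inst$crf_id, vn, sep = ".")
        if (is.null(values[[qv]])) values[[qv]] <- inst$values[[vn]]
      }
    }
  }
  values
}

completedCrfIds <- function(store, pid) {
  done <- Filter(function(i) i$status %in% c("complete", "signed"),
                 crfInstancesFor(store, pid))
  unique(vapply(done, function(i) i$crf_id, character(1)))
}

#' Evaluate a participant's eligibility
#'
#' Runs every criterion under three-valued logic against the values
#' currently readable (completed CRFs plus registry-derived age). A
#' criterion that evaluates `FALSE` fails immediately — even before its
#' other predicate CRFs exist — so a single negative criterion excludes the
#' participant at once. A criterion counts as passed only when it evaluates
#' `TRUE` *and* all of its predicate CRFs are complete; overall eligibility
#' requires every criterion passed and every predicate CRF complete (with
#' zero criteria this holds vacuously). The decision is terminal:
#' re-evaluation never flips an eligible/ineligible state unless `force`
#' (the audited data-correction path) is set.
#'
#' Evaluation is deterministic and order-independent: the same set of
#' completed CRFs yields the same state whatever order they completed in.
#'
#' @param store an `edc_store`.
#' @param defn compiled study definition.
#' @param pid participant id.
#' @param force re-evaluate from scratch even over a terminal state
#'   (requires an audited edit upstream).
#' @return the eligibility state: `list(per_criterion, overall, decided_at)`.
#' @export
evaluateEligibility <- function(store, defn, pid, force = FALSE) {
  cur <- store$state$eligibility[[pid]]
  if (!force && !is.null(cur) && cur$overall %in% c("eligible", "ineligible")) {
    return(cur)
  }
  values <- eligibilityValues(store, defn, pid)
  done <- completedCrfIds(store, pid)
  preds <- predicateCrfs(defn)
  per <- list()
  for (kid in names(defn$criteria)) {
    res <- evalRuleExpression(
      parseRuleExpression(defn$criteria[[kid]]$expression, "qualified"),
      values)
    per[[kid]] <- if (isFALSE(res)) {
      "fail"
    } else if (isTRUE(res) && all(preds[[kid]] %in% done)) {
      "pass"
    } else {
      "pending"
    }
  }
  all_preds_done <- all(unique(unlist(preds)) %in% done)
  overall <- if (any(unlist(per) == "fail")) {
    "ineligible"
  } else if ((length(per) == 0 || all(unlist(per) == "pass")) && all_preds_done) {
    "eligible"
  } else {
    "pending"
  }
  state <- list(per_criterion = per, overall = overall,
                decided_at = if (overall == "pending") NULL else formatTs(store$clock()))
  if (!identical(cur$per_criterion, per)) {
    recordChange(store, "eligibility", pid, "per_criterion", per, "@system",
                 meta = list(participant = pid))
  }
  if (!identical(cur$overall, overall)) {
    recordChange(store, "eligibility", pid, "overall", overall, "@system",
                 meta = list(participant = pid))
    if (!is.null(state$decided_at)) {
      recordChange(store, "eligibility", pid, "decided_at", state$decided_at,
                   "@system", meta = list(participant = pid))
    }
    p <- store$state$participants[[pid]]
    if (overall %in% c("eligible", "ineligible") &&
        p$status %in% c("registered", "screening")) {
      setParticipantStatus(store, pid, overall, "@system")
    } else if (force && overall %in% c("eligible", "ineligible") &&
               !identical(p$status, overall) &&
               p$status %in% c("eligible", "ineligible")) {
      setParticipantStatus(store, pid, overall, "@system", force = TRUE)
    }
  }
  store$state$eligibility[[pid]]
}

#' Human-readable per-criterion eligibility report
#'
#' Never mutates state. Pending criteria name the predicate CRFs still
#' missing.
#'
#' @param store an `edc_store`.
#' @param defn compiled study definition.
#' @param pid participant id.
#' @return data frame with columns `criterion_id`, `status`, `description`,
#'   `variables`, `missing_crfs`.
#' @export
eligibilityReport <- function(store, defn, pid) {
  st <- store$state$eligibility[[pid]]
  done <- completedCrfIds(store, pid)
  preds <- predicateCrfs(defn)
  rows <- lapply(names(defn$criteria), function(kid) {
    parsed <- parseRuleExpression(defn$criteria[[kid]]$expression, "qualified")
    missing <- setdiff(preds[[kid]], done)
    data.frame(
      criterion_id = kid,
      status = st$per_criterion[[kid]] %||% "pending",
      description = defn$criteria[[kid]]$description,
      variables = paste(parsed$vars, collapse = ", "),
      missing_crfs = paste(missing, collapse = ", "),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, c(rows, list(stringsAsFactors = FALSE)))
  if (is.null(out)) {
    out <- data.frame(criterion_id = character(0), status = character(0),
                      description = character(0), variables = character(0),
                      missing_crfs = character(0), stringsAsFactors = FALSE)
  }
  attr(out, "overall") <- st$overall %||% "pending"
  out
}
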