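## Shared fixtures and rigs. Fixture workbooks are built once per test run.

.fx_cache <- new.env(parent = emptyenv())

getFixture <- function(name) {
  if (is.null(.fx_cache[[name]])) .fx_cache[[name]] <- buildFixture(name)
  .fx_cache[[name]]
}

## a store pre-provisioned with a data manager and two research assistants
rigStore <- function(defn, device = "01", clock = NULL) {
  st <- if (is.null(clock)) createStore(defn, device) else
    createStore(defn, device, clock = clock)
  addUser(st, "dm", "dm-pw", "data-manager")
  dm <- authenticate(st, "dm", "dm-pw")
  addUser(st, "ra", "ra-pw", "research-assistant", session = dm)
  addUser(st, "ra2", "ra-pw", "research-assistant", session = dm)
  list(store = st, dm = dm, ra = authenticate(st, "ra", "ra-pw"))
}

## minimal ad-hoc study: n CRFs each holding one required integer x,
## all at one visit, everything pre-consent, optional criteria
miniSheets <- function(crf_ids = c("a", "b"), criteria = character(0),
                       scheduled = TRUE) {
  forms <- data.frame(crf_id = crf_ids,
                      title_en = paste("CRF", crf_ids),
                      signature_slots = "1", is_consent_form = "",
                      consent_class = "", pre_consent = "1",
                      stringsAsFactors = FALSE)
  dictionary <- data.frame(crf_id = crf_ids, name = "x", type = "integer",
                           label_en = "x", choices = "", soft_low = "",
                           soft_high = "", hard_low = "", hard_high = "",
                           required = "1", high_importance = "",
                           identifying = "", unit = "", skip_if = "",
                           stringsAsFactors = FALSE)
  visits <- data.frame(visit_id = "v1", label = "Visit 1",
                       order_index = "1",
                       scheduled = if (scheduled) "1" else "0",
                       stringsAsFactors = FALSE)
  schedule <- data.frame(visit_id = "v1", crf_id = crf_ids, mode = "always",
                         stringsAsFactors = FALSE)
  ids <- data.frame(scope = "participant", position = c("1", "2"),
                    component = c("device-code", "sequential"),
                    value = c("2", "4"), stringsAsFactors = FALSE)
  sheets <- list(study = data.frame(study_code = "MINI", version = "1",
                                    default_language = "en",
                                    sync_cadence = "daily",
                                    stringsAsFactors = FALSE),
                 forms = forms, dictionary = dictionary, visits = visits,
                 schedule = schedule, ids = ids)
  if (length(criteria) > 0) {
    sheets$criteria <- data.frame(criterion_id = names(criteria),
                                  expression = unname(criteria),
                                  description = names(criteria),
                                  stringsAsFactors = FALSE)
  }
  sheets
}

miniStudy <- function(...) loadStudyDefinition(miniSheets(...))

## canonical, comparable snapshot of the synchronized portion of a store
stateSnapshot <- function(store) {
  ents <- list()
  for (entity in c("users", "devices", "households", "participants",
                   "visits", "crfs", "eligibility", "allocations")) {
    e <- store$state[[entity]]
    ents[[entity]] <- if (length(e) == 0) list() else e[order(names(e))]
  }
  ents
}

## independent oracle: qualified crf references by raw token scan
tokenScanCrfs <- function(expression) {
  toks <- regmatches(expression,
                     gregexpr("[A-Za-z_][A-Za-z0-9_]*\\.[A-Za-z_][A-Za-z0-9_]*",
                              expression))[[1]]
  crfs <- unique(vapply(strsplit(toks, ".", fixed = TRUE), `[[`, "", 1))
  setdiff(crfs, "participant")
}

## drive one participant through the surveillance screening flow
surveilParticipant <- function(rig, fx, age_years = 30, pregnant = "0",
                               lactating = "0") {
  defn <- fx$definition
  st <- rig$store
  hh <- registerHousehold(st, defn, rig$ra, list())
  pid <- registerParticipant(st, defn, rig$ra,
                             dobExact(Sys.Date() - round(age_years * 365.25) - 10),
                             household_id = hh)
  list(pid = pid, hh = hh)
}

fillAndComplete <- function(st, defn, ses, key, values, sign_as = NULL) {
  for (vn in names(values)) {
    enterValue(st, defn, ses, key, vn, values[[vn]], acknowledge = TRUE)
  }
  completeCrf(st, defn, ses, key)
  if (!is.null(sign_as)) {
    for (s in sign_as) signCrf(st, defn, key, s$username, s$password)
  }
  invisible(key)
}
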